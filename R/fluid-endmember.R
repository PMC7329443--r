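#' Zero-Mg endmember composition of a vent fluid
#'
#' Hydrothermal endmember fluids are operationally Mg-free, while ambient
#' seawater carries ~53 mmol/kg Mg, so inadvertent seawater entrainment
#' during sampling dilutes every species along a conservative mixing line.
#' Regressing each species' concentration on measured Mg across replicate
#' samples and reading the intercept at Mg = 0 recovers the endmember
#' composition — the standard treatment for high-temperature submarine vent
#' fluids.
#'
#' Below-detection values (NA) are excluded from the fit, not substituted.
#' Negative intercepts are clipped to 0 and flagged. When every sample sits
#' at Mg = 0 the regression degenerates to the sample mean; identical
#' nonzero Mg across samples is an error (no leverage to extrapolate).
#'
#' @param samples `data.frame` of fluid samples for ONE vent: a column
#'   `Mg` plus one column per species (concentrations; units carried
#'   through). Non-species columns (`sample_id`, `phi`, `temperature`,
#'   `pH`) are ignored.
#' @param species Species to extrapolate; default every numeric column
#'   except Mg and the bookkeeping columns.
#' @return `data.frame` (class `endmember_fit`): `species`, `endmember`
#'   (intercept at Mg = 0), `slope`, `se` (standard error of the
#'   intercept), `n`, `extrapolated`, `clipped`.
#' @export
extrapolate_endmember <- function(samples, species = NULL) {
  stopifnot("Mg" %in% names(samples))
  drop_cols <- c("sample_id", "vent_id", "phi", "temperature", "pH", "Mg")
  species <- species %||% setdiff(names(samples)[vapply(samples, is.numeric,
                                                        TRUE)], drop_cols)
  mg <- samples$Mg
  if (length(mg) < 2) stop("extrapolate_endmember: need >= 2 samples")
  rows <- lapply(species, function(sp) {
    y <- samples[[sp]]
    ok <- !is.na(y) & !is.na(mg)
    x <- mg[ok]; y <- y[ok]
    if (length(y) < 2)
      return(data.frame(species = sp, endmember = NA_real_,
                        slope = NA_real_, se = NA_real_, n = length(y),
                        extrapolated = FALSE, clipped = FALSE,
                        stringsAsFactors = FALSE))
    if (var(x) == 0) {
      if (all(x == 0)) {
        # all samples already at the endmember: intercept-only fit
        return(data.frame(species = sp, endmember = mean(y), slope = 0,
                          se = stats::sd(y) / sqrt(length(y)), n = length(y),
                          extrapolated = FALSE, clipped = FALSE,
                          stringsAsFactors = FALSE))
      }
      stop("extrapolate_endmember: no Mg leverage (identical nonzero Mg)")
    }
    n <- length(y)
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    em <- mean(y) - slope * mean(x)
    res <- y - em - slope * x
    sigma2 <- if (n > 2) sum(res^2) / (n - 2) else 0
    se <- sqrt(sigma2 * (1 / n + mean(x)^2 / sxx))
    clip <- em < 0
    data.frame(species = sp, endmember = max(0, em), slope = slope,
               se = se, n = n, extrapolated = TRUE, clipped = clip,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("endmember_fit", "data.frame")
  out
}

#' Measured-composition summary for a diffuse or inactive vent
#'
#' When Mg varies little across samples (seawater already entrained below
#' the seafloor), extrapolation is not meaningful and the measured
#' composition is reported instead, with enrichment/depletion relative to
#' seawater.
#'
#' @param samples Fluid sample table (see [extrapolate_endmember()]).
#' @param seawater Named numeric vector of seawater concentrations
#'   (default [seawater_reference()]).
#' @param species Species to summarize; default as in
#'   [extrapolate_endmember()].
#' @return `data.frame`: `species`, `measured` (mean), `seawater`,
#'   `relative` (measured/seawater, NA where seawater is 0 or unknown).
#' @export
measured_composition <- function(samples, seawater = seawater_reference(),
                                 species = NULL) {
  drop_cols <- c("sample_id", "vent_id", "phi", "temperature", "pH")
  species <- species %||% setdiff(names(samples)[vapply(samples, is.numeric,
                                                        TRUE)], drop_cols)
  meas <- vapply(species, function(sp) mean(samples[[sp]], na.rm = TRUE), 0)
  sw <- seawater[species]
  data.frame(species = species, measured = meas,
             seawater = unname(sw),
             relative = ifelse(!is.na(sw) & sw > 0, meas / sw, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Reported pH of a vent fluid
#'
#' The reported pH (25 degrees C) is the lowest value measured across the
#' samples; pH is never regressed against Mg.
#'
#' @param samples Fluid sample table with a `pH` column.
#' @return Single numeric pH.
#' @export
report_ph <- function(samples) {
  if (!"pH" %in% names(samples) || all(is.na(samples$pH)))
    stop("report_ph: no pH measurements")
  min(samples$pH, na.rm = TRUE)
}

#' Conservative-mixing expectation
#'
#' Concentration expected at seawater fraction `phi` when an endmember
#' fluid blends with seawater without reaction:
#' `c(phi) = phi * c_sw + (1 - phi) * c_em`. The depletion of a measured
#' value relative to this expectation, `(expected - measured)/expected`,
#' quantifies abiotic plus biotic consumption.
#'
#' @param endmember,seawater Named numeric vectors (aligned by name).
#' @param phi Seawater fraction in [0, 1].
#' @return Named numeric vector of expected concentrations.
#' @export
conservative_mixing <- function(endmember, seawater, phi) {
  stopifnot(phi >= 0, phi <= 1)
  species <- union(names(endmember), names(seawater))
  em <- setNames(ifelse(species %in% names(endmember),
                        endmember[species], 0), species)
  sw <- setNames(ifelse(species %in% names(seawater),
                        seawater[species], 0), species)
  phi * sw + (1 - phi) * em
}

#' Ambient seawater reference composition
#'
#' Background seawater concentrations used for mixing calculations:
#' Mg 53.0, K 9.95, Ca 9.98, Cl 537, SO4 27.7, CO2 2.3 (mmol/kg),
#' H2S 0, CH4 0, H2 0.
#'
#' @return Named numeric vector.
#' @export
seawater_reference <- function() {
  c(Mg = 53.0, K = 9.95, Ca = 9.98, Cl = 537, SO4 = 27.7, CO2 = 2.3,
    H2S = 0, CH4 = 0, H2 = 0)
}
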