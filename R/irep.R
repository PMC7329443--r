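#' Sliding-window coverage from a finer track
#'
#' Mean depth over sliding windows, computed per contig and concatenated.
#' The input track's cells must tile each contig contiguously; `window` and
#' `slide` must be multiples of the cell size. Contigs shorter than one
#' window are dropped with a message (an error if nothing survives).
#'
#' @param track A `coverage_track` (see [generate_coverage_track()] or
#'   [read_bedgraph()]).
#' @param window Window size in bp (default 5000).
#' @param slide Step between window starts in bp (default 100);
#'   `window >= slide > 0`.
#' @return A `coverage_track` of window means with attributes `window` and
#'   `slide`.
#' @export
window_coverage <- function(track, window = 5000, slide = 100) {
  stopifnot(inherits(track, "coverage_track") || is.data.frame(track),
            window >= slide, slide > 0)
  cell <- attr(track, "cell") %||% unique(track$end - track$start)[1]
  if (window %% cell != 0 || slide %% cell != 0)
    stop("window_coverage: window and slide must be multiples of the cell size (",
         cell, " bp)")
  wc <- window %/% cell
  sc <- slide %/% cell
  pieces <- lapply(split(track, track$contig), function(tr) {
    tr <- tr[order(tr$start), ]
    k <- nrow(tr)
    if (k < wc) return(NULL)
    cs <- c(0, cumsum(tr$depth))
    starts <- seq(1L, k - wc + 1L, by = sc)
    data.frame(contig = tr$contig[1],
               start = tr$start[starts],
               end = tr$start[starts] + window,
               depth = (cs[starts + wc] - cs[starts]) / wc,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(pieces, is.null, TRUE))
  if (dropped > 0)
    message("window_coverage: dropped ", dropped,
            " contig(s) shorter than one window")
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (!length(pieces)) stop("window_coverage: every contig shorter than window")
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, class = c("coverage_track", "data.frame"),
            cell = cell, window = window, slide = slide)
}

#' Index of replication from a coverage trend
#'
#' Implements the coverage-trend estimator for bacterial populations with a
#' single replication origin: window depths are sorted ascending (recovering
#' origin-distance order irrespective of contig arrangement), each window is
#' anchored at its rank fraction t in [0, 1] over all windows, the lowest
#' and highest `trim` fraction are dropped, and ordinary least squares of
#' log2(depth) on t gives the slope; iRep = 2^slope. A value of 1 means no
#' replication; 1.5 means half the cells carry one replication fork; 2 means
#' all of them do.
#'
#' @param track A `coverage_track`, or a bare numeric vector of window
#'   depths.
#' @param trim Fraction trimmed from each tail after sorting (default
#'   0.05).
#' @param min_cov Minimum median depth (x-fold, default 5); below it the
#'   status is `"insufficient coverage"` and no value is returned.
#' @param min_windows Minimum number of windows (default 10).
#' @return Object of class `irep_fit`: list with `irep`, `slope`, `r2`,
#'   `n_windows`, `status` (`"ok"` / `"insufficient coverage"`) and
#'   `flags` (e.g. `"zero-depth windows given pseudodepth 0.5"`).
#' @export
estimate_irep <- function(track, trim = 0.05, min_cov = 5,
                          min_windows = 10) {
  depths <- if (is.data.frame(track)) track$depth else as.numeric(track)
  stopifnot(trim >= 0, trim < 0.5)
  flags <- character(0)
  if (length(depths) < min_windows)
    return(irep_fit(NA, NA, NA, length(depths), "insufficient coverage",
                    "fewer windows than min_windows"))
  if (median(depths) < min_cov)
    return(irep_fit(NA, NA, NA, length(depths), "insufficient coverage",
                    flags))
  o <- sort(depths)
  k <- length(o)
  t <- if (k > 1) (seq_len(k) - 1) / (k - 1) else 0.5
  lo <- floor(k * trim)
  idx <- (lo + 1L):(k - lo)
  o <- o[idx]
  t <- t[idx]
  if (any(o <= 0)) {
    o[o <= 0] <- 0.5
    flags <- c(flags, "zero-depth windows given pseudodepth 0.5")
  }
  y <- log2(o)
  fit <- lm.fit(cbind(1, t), y)
  slope <- fit$coefficients[[2]]
  r2 <- if (var(y) > 0) 1 - sum(fit$residuals^2) / sum((y - mean(y))^2) else 1
  irep_fit(2^slope, slope, r2, length(y), "ok", flags)
}

irep_fit <- function(irep, slope, r2, n, status, flags = character(0)) {
  structure(list(irep = irep, slope = slope, r2 = r2, n_windows = n,
                 status = status, flags = flags), class = "irep_fit")
}

#' @export
print.irep_fit <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("iRep = %.3f  (slope %.4f, R^2 %.3f, %d windows%s)\n",
                x$irep, x$slope, x$r2, x$n_windows,
                if (length(x$flags)) paste0("; ", paste(x$flags,
                                                        collapse = "; "))
                else ""))
  else cat(sprintf("iRep: %s (%d windows)\n", x$status, x$n_windows))
  invisible(x)
}

#' @export
coef.irep_fit <- function(object, ...) {
  c(irep = object$irep, slope = object$slope)
}

#' Replication rates for a set of MAGs
#'
#' Applies the scaffolds-per-Mb eligibility filter, then estimates iRep per
#' bin from the coverage windows of its member contigs.
#'
#' @param bins Bin table with `bin_id`, `scaffold_count`, `total_length`,
#'   `domain`.
#' @param membership `data.frame(bin_id, contig_id)`; coverage-track contig
#'   names must match `contig_id`.
#' @param coverage A `coverage_track` covering the bins' contigs (cell
#'   resolution).
#' @param window,slide,trim,min_cov Passed to [window_coverage()] and
#'   [estimate_irep()].
#' @param max_per_mb Eligibility threshold (default 175 scaffolds/Mb).
#' @return `data.frame`: `bin_id`, `irep`, `slope`, `r2`, `windows`,
#'   `status` (`"ok"`, `"ineligible"`, `"insufficient coverage"`).
#' @export
irep_for_bins <- function(bins, membership, coverage, window = 5000,
                          slide = 100, trim = 0.05, min_cov = 5,
                          max_per_mb = 175) {
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    b <- bins[i, ]
    base <- data.frame(bin_id = b$bin_id, irep = NA_real_,
                       slope = NA_real_, r2 = NA_real_, windows = 0L,
                       status = "ineligible", stringsAsFactors = FALSE)
    if (!irep_eligible(b$scaffold_count, b$total_length,
                       b$domain %||% "Bacteria", max_per_mb))
      return(base)
    ctg <- membership$contig_id[membership$bin_id == b$bin_id]
    sub <- coverage[coverage$contig %in% ctg, , drop = FALSE]
    if (nrow(sub) == 0) {
      base$status <- "insufficient coverage"
      return(base)
    }
    attr(sub, "cell") <- attr(coverage, "cell")
    class(sub) <- class(coverage)
    est <- tryCatch(
      estimate_irep(window_coverage(sub, window, slide), trim, min_cov),
      error = function(e) irep_fit(NA, NA, NA, 0L, "insufficient coverage"))
    data.frame(bin_id = b$bin_id, irep = est$irep, slope = est$slope,
               r2 = est$r2, windows = est$n_windows, status = est$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
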