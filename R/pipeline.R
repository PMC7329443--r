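#' Configuration for the two-community comparison workflow
#'
#' Collects input paths and per-stage parameters. Defaults follow the
#' workflow's standard thresholds: 3-kb minimum contig length for MAG
#' abundance, completeness >= 70 / contamination <= 9, AAI 99 for
#' dereplication, 175 scaffolds/Mb for iRep eligibility, FDR alpha 0.05.
#' Unknown parameter names are rejected.
#'
#' @param genes_a,genes_b Gene table TSVs for the two samples.
#' @param contigs,bins,membership,aai MAG workflow inputs (TSV; see
#'   [write_community_files()] for the layouts).
#' @param coverage bedGraph coverage track.
#' @param fluids Optional fluids CSV.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the report.
#' @param params Named list overriding defaults: `alpha`, `min_contig_len`,
#'   `min_completeness`, `max_contamination`, `aai_cutoff`, `max_per_mb`,
#'   `gc_mad_k`, `depth_fold`, `tetra_pct`, `window`, `slide`, `trim`,
#'   `min_cov`, `read_length`.
#' @return A `run_config` list.
#' @export
run_config <- function(genes_a, genes_b, contigs, bins, membership, aai,
                       coverage, fluids = NULL, out_dir = tempfile("ventrun"),
                       seed = 42, params = list()) {
  defaults <- list(alpha = 0.05, min_contig_len = 3000,
                   min_completeness = 70, max_contamination = 9,
                   aai_cutoff = 99, max_per_mb = 175,
                   gc_mad_k = 3, depth_fold = 3, tetra_pct = 0.98,
                   window = 5000, slide = 100, trim = 0.05, min_cov = 5,
                   read_length = 100)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("run_config: unknown parameter(s): ", paste(unknown, collapse = ", "))
  structure(list(genes_a = genes_a, genes_b = genes_b, contigs = contigs,
                 bins = bins, membership = membership, aai = aai,
                 coverage = coverage, fluids = fluids, out_dir = out_dir,
                 seed = seed, params = modifyList(defaults, params)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full two-community comparison workflow
#'
#' Executes abundance normalization, differential testing, MAG refinement,
#' MAG quantification, iRep estimation, pathway classification of gene
#' content (when taxa/pathway annotations are present in the gene tables)
#' and, if a fluids table is given, endmember chemistry. Writes all stage
#' tables plus an effective-config file under `config$out_dir` and returns
#' them invisibly as a structured report. Any stage failure aborts with a
#' stage-tagged message.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list (class `vent_report`) of stage results:
#'   `abundance_a`, `abundance_b`, `diff`, `refinement`, `mag_abundance`,
#'   `irep`, `fluids` (or NULL), `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("genes_a", "genes_b", "contigs", "bins", "membership", "aai")) {
    if (!file.exists(config[[f]]))
      stop(sprintf("[input] missing file for '%s': %s", f, config[[f]]))
  }
  p <- config$params
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(c(config[setdiff(names(config), "params")],
                     list(params = p)),
                   file.path(config$out_dir, "effective_config.yml"))

  ga <- stage("abundance", read_gene_table(config$genes_a, p$read_length))
  gb <- stage("abundance", read_gene_table(config$genes_b, p$read_length))
  aa <- stage("abundance", normalize_abundance(ga))
  ab <- stage("abundance", normalize_abundance(gb))
  write_tsv(aa, file.path(config$out_dir, "abundance_A.tsv"))
  write_tsv(ab, file.path(config$out_dir, "abundance_B.tsv"))

  dif <- stage("diffstats",
               compare_metagenomes(ga, gb, alpha = p$alpha))
  write_tsv(as.data.frame(dif), file.path(config$out_dir, "diff.tsv"),
            comments = sprintf("alpha = %g, BH-adjusted", p$alpha))

  contigs <- stage("mags", read_contig_table(config$contigs))
  bins <- stage("mags", read_tsv(config$bins))
  membership <- stage("mags", read_tsv(config$membership))
  aai_df <- stage("mags", read_tsv(config$aai))
  aai <- as.matrix(aai_df[, -1])
  rownames(aai) <- aai_df[[1]]
  ref <- stage("mags", refine_bins(
    bins, membership, contigs, aai,
    gc_mad_k = p$gc_mad_k, depth_fold = p$depth_fold,
    tetra_pct = p$tetra_pct, aai_cutoff = p$aai_cutoff,
    min_completeness = p$min_completeness,
    max_contamination = p$max_contamination))
  write_tsv(ref$bins, file.path(config$out_dir, "refined_bins.tsv"))
  write_tsv(ref$removed_contigs,
            file.path(config$out_dir, "removed_contigs.tsv"))

  mab <- stage("mags", mag_relative_abundance(ref$membership, contigs,
                                              p$min_contig_len))
  write_tsv(data.frame(bin_id = names(mab), fraction = as.numeric(mab)),
            file.path(config$out_dir, "abundance_mags.tsv"),
            comments = sprintf("unbinned fraction = %.4f",
                               attr(mab, "unbinned")))

  cov <- stage("irep", read_bedgraph(config$coverage))
  irep <- stage("irep", irep_for_bins(
    ref$bins, ref$membership, cov, window = p$window, slide = p$slide,
    trim = p$trim, min_cov = p$min_cov, max_per_mb = p$max_per_mb))
  write_tsv(irep, file.path(config$out_dir, "irep.tsv"))

  fl <- NULL
  if (!is.null(config$fluids)) {
    fls <- stage("fluids", read.csv(config$fluids, check.names = FALSE))
    fl <- stage("fluids", extrapolate_endmember(fls))
    write_tsv(as.data.frame(fl), file.path(config$out_dir, "endmember.tsv"))
  }

  report <- structure(list(abundance_a = aa, abundance_b = ab, diff = dif,
                           refinement = ref, mag_abundance = mab,
                           irep = irep, fluids = fl,
                           paths = list.files(config$out_dir,
                                              full.names = TRUE)),
                      class = "vent_report")
  invisible(report)
}

#' @export
print.vent_report <- function(x, ...) {
  cat("Two-community comparison report\n")
  cat(sprintf("  genes tested: %d (%d significant)\n", nrow(x$diff),
              sum(x$diff$significant)))
  cat(sprintf("  qualified MAGs: %d\n", nrow(x$refinement$bins)))
  cat(sprintf("  iRep estimates: %d ok / %d total\n",
              sum(x$irep$status == "ok"), nrow(x$irep)))
  if (!is.null(x$fluids))
    cat(sprintf("  endmember species: %d\n", nrow(x$fluids)))
  invisible(x)
}
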