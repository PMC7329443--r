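#' Length-normalized per-million gene abundance
#'
#' For each gene g with mapped reads r_g and length L_g, the normalized
#' abundance is
#' \deqn{A_g = \frac{r_g / L_g}{\sum_h r_h / L_h} \times 10^6,}
#' i.e. reads are first divided by gene length and then rescaled so the
#' sample sums to one million (a TPM-style unit). The denominator sums over
#' every gene in the table, not just a reported subset; pass a pre-filtered
#' table for key-genes-only normalization.
#'
#' @param genes Gene table with columns `gene_id`, `length`, `reads`
#'   (e.g. from [generate_gene_table()] or [read_gene_table()]).
#' @return The input table with an `abundance` column (per-million units)
#'   and attribute `total_reads`.
#' @export
normalize_abundance <- function(genes) {
  stopifnot(all(c("gene_id", "length", "reads") %in% names(genes)),
            all(genes$length > 0), all(genes$reads >= 0))
  if (nrow(genes) == 0L || sum(genes$reads) == 0)
    stop("normalize_abundance: empty sample (no mapped reads)")
  rate <- genes$reads / genes$length
  genes$abundance <- rate / sum(rate) * 1e6
  attr(genes, "total_reads") <- sum(genes$reads)
  genes
}

#' Taxonomic attribution of a functional gene
#'
#' Splits the total sequencing depth of all genes carrying `symbol` across
#' their taxon labels: the fraction for taxon t is the summed depth of its
#' genes divided by the summed depth of all genes with that symbol.
#'
#' @param genes Gene table with columns `symbol`, `taxon` and `depth` (or
#'   `reads` + `length`, from which depth is derived using the table's
#'   `read_length` attribute, default 100).
#' @param symbol Gene symbol to attribute.
#' @return Named numeric vector of fractions summing to 1 (empty, with a
#'   warning, when the symbol is absent).
#' @export
taxon_breakdown <- function(genes, symbol) {
  stopifnot(all(c("symbol", "taxon") %in% names(genes)))
  if (!"depth" %in% names(genes)) {
    rl <- attr(genes, "read_length") %||% 100
    genes$depth <- genes$reads * rl / genes$length
  }
  sub <- genes[genes$symbol == symbol, ]
  if (nrow(sub) == 0L) {
    warning(sprintf("taxon_breakdown: symbol '%s' not present", symbol))
    return(setNames(numeric(0), character(0)))
  }
  agg <- tapply(sub$depth, sub$taxon, sum)
  frac <- agg / sum(agg)
  sort(setNames(as.numeric(frac), names(frac)), decreasing = TRUE)
}

#' Depth-based taxonomic summary of reconstructed rRNA genes
#'
#' Relative abundance of each phylum-level label (class level for
#' Proteobacteria, if the input is labelled that way) as its share of the
#' total sequencing depth of all reconstructed 16S rRNA genes. Records with
#' an empty or missing label are pooled into an `"unclassified"` bucket
#' that stays in the denominator.
#'
#' @param rrna Table with columns `id`, `depth`, `label`.
#' @param per_gene_average If `TRUE`, each taxon contributes its mean (not
#'   summed) per-gene depth before normalization — an alternative reading
#'   of "average sequencing depth"; the two agree when every taxon has one
#'   gene.
#' @return Named numeric vector of relative abundances summing to 1.
#' @export
summarize_rrna <- function(rrna, per_gene_average = FALSE) {
  stopifnot(all(c("depth", "label") %in% names(rrna)), nrow(rrna) >= 1)
  lab <- as.character(rrna$label)
  lab[is.na(lab) | lab == ""] <- "unclassified"
  agg <- if (per_gene_average) tapply(rrna$depth, lab, mean)
         else tapply(rrna$depth, lab, sum)
  frac <- agg / sum(agg)
  sort(setNames(as.numeric(frac), names(frac)), decreasing = TRUE)
}

#' How representative are recovered MAGs of the whole community?
#'
#' Ranks single-copy marker genes (e.g. ribosomal protein S3) by sequencing
#' depth and counts how many of the `top_n` most abundant markers fall
#' inside any retained bin — the paper-style "x of the top 50" report.
#' Depth ties break by gene id (lexicographic) for determinism.
#'
#' @param markers Table with columns `gene_id` and `depth`.
#' @param binned_ids Character vector of marker gene ids found in bins.
#' @param top_n Number of top markers to consider (default 50).
#' @return List with `count` (markers in bins among the top), `top_n`
#'   (actually used, capped at the marker count) and `note`.
#' @export
rps3_representativeness <- function(markers, binned_ids, top_n = 50) {
  stopifnot(all(c("gene_id", "depth") %in% names(markers)), top_n >= 1)
  ord <- order(-markers$depth, markers$gene_id)
  note <- ""
  if (nrow(markers) < top_n) {
    note <- sprintf("only %d markers available (top_n = %d)",
                    nrow(markers), top_n)
    top_n <- nrow(markers)
  }
  top <- markers$gene_id[ord][seq_len(top_n)]
  list(count = sum(top %in% binned_ids), top_n = top_n, note = note)
}
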