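#' Canonical tetranucleotides (reverse-complement collapsed)
#'
#' The 256 DNA 4-mers collapse into 136 classes when each word is pooled
#' with its reverse complement (16 words are their own reverse complement).
#'
#' @return Character vector of the 136 lexicographically smallest class
#'   representatives.
#' @export
canonical_tetramers <- function() {
  b <- c("A", "C", "G", "T")
  all4 <- apply(expand.grid(b, b, b, b, stringsAsFactors = FALSE)[, 4:1],
                1, paste0, collapse = "")
  rc <- revcomp_chr(all4)
  sort(unique(pmin(all4, rc)))
}

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGT", "TGCA", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Genomic signature of a contig
#'
#' GC content over unambiguous bases and the reverse-complement-collapsed
#' tetranucleotide frequency vector (sliding 4-mers; windows containing N
#' are skipped; normalized to sum 1).
#'
#' @param sequence Nucleotide string over A/C/G/T/N (case-insensitive), or
#'   a `Biostrings::DNAString`.
#' @param depth Mean sequencing depth of the contig (carried through).
#' @param contig_id Optional id (carried through).
#' @return List with `contig_id`, `length`, `gc`, `depth` and `tetra`
#'   (named numeric of length 136 summing to 1).
#' @export
compute_contig_stats <- function(sequence, depth = NA_real_,
                                 contig_id = NA_character_) {
  s <- Biostrings::DNAString(toupper(as.character(sequence)))
  if (length(s) < 4) stop("compute_contig_stats: sequence shorter than 4 bp")
  base <- Biostrings::alphabetFrequency(s)[c("A", "C", "G", "T")]
  if (sum(base) == 0) stop("compute_contig_stats: no unambiguous bases")
  gc <- sum(base[c("G", "C")]) / sum(base)
  cnt <- Biostrings::oligonucleotideFrequency(s, width = 4, step = 1)
  kmers <- canonical_tetramers()
  canon <- pmin(names(cnt), revcomp_chr(names(cnt)))
  pooled <- tapply(cnt, canon, sum)[kmers]
  pooled[is.na(pooled)] <- 0
  if (sum(pooled) == 0) stop("compute_contig_stats: no N-free 4-mer window")
  list(contig_id = contig_id, length = length(s), gc = gc, depth = depth,
       tetra = pooled / sum(pooled))
}

#' Should two candidate bins be merged?
#'
#' Two bins may be combined only when they carry the same taxonomic label
#' and the merged bin's quality would improve enough: completeness up by at
#' least 10 percentage points over the better member while contamination
#' rises by at most 1 point over the worse member. Thresholds are read as
#' percentage points (marker-set quality estimates are reported in percent
#' units; a relative-percent reading would make the contamination guard
#' nearly vacuous for clean bins).
#'
#' @param qual_a,qual_b,qual_merged Numeric `c(completeness, contamination)`
#'   in percent for the two members and the hypothetical merged bin.
#' @param tax_a,tax_b Taxonomy labels.
#' @param min_gain,max_rise Thresholds in percentage points (defaults 10
#'   and 1).
#' @return `TRUE`/`FALSE` with attribute `reason`.
#' @export
merge_decision <- function(qual_a, qual_b, qual_merged, tax_a, tax_b,
                           min_gain = 10, max_rise = 1) {
  stopifnot(length(qual_a) == 2, length(qual_b) == 2, length(qual_merged) == 2)
  if (!identical(tax_a, tax_b))
    return(structure(FALSE, reason = "different taxonomy"))
  gain <- qual_merged[1] - max(qual_a[1], qual_b[1])
  rise <- qual_merged[2] - max(qual_a[2], qual_b[2])
  if (gain < min_gain)
    return(structure(FALSE,
                     reason = sprintf("completeness gain %.1f < %g", gain,
                                      min_gain)))
  if (rise > max_rise)
    return(structure(FALSE,
                     reason = sprintf("contamination rise %.1f > %g", rise,
                                      max_rise)))
  structure(TRUE, reason = "accept")
}

#' Remove contigs with divergent genomic properties from a bin
#'
#' A member contig is flagged when any of three signatures diverges from
#' the bin consensus: GC more than `gc_mad_k` scaled MADs from the bin
#' median; depth outside `[median/depth_fold, median*depth_fold]`; or
#' Manhattan distance between its tetranucleotide vector and the bin's
#' length-weighted mean vector above the `tetra_pct` quantile of within-bin
#' distances. Because a continuous distance distribution always has
#' observations above its 98th percentile, the tetra criterion additionally
#' requires the distance to exceed `tetra_min_fold` times the median
#' within-bin distance — without this guard the rule would shave the most
#' distant contig off every (even perfectly homogeneous) bin on every pass
#' and the workflow could not be idempotent. Bins with fewer than 3 members
#' are left untouched.
#'
#' @param members Contig ids belonging to the bin.
#' @param contigs Contig stats table (columns `contig_id`, `length`, `gc`,
#'   `depth`, and a `tetra` matrix column), e.g. from
#'   [generate_bin_metadata()] or rows built with
#'   [compute_contig_stats()].
#' @param gc_mad_k,depth_fold,tetra_pct Thresholds (defaults 3, 3, 0.98).
#' @param tetra_min_fold Robustness guard on the tetra criterion (default
#'   3; see Details).
#' @param gc_min_diff Absolute floor on the GC criterion (default 0.02):
#'   a GC deviation under two percentage points is within-genome variation
#'   and never treated as evidence of foreign origin, which also keeps the
#'   MAD rule from re-firing on already-clean bins.
#' @return List with `kept`, `removed` (contig ids) and `reasons` (named
#'   character, comma-joined per removed contig).
#' @export
filter_outlier_contigs <- function(members, contigs, gc_mad_k = 3,
                                   depth_fold = 3, tetra_pct = 0.98,
                                   tetra_min_fold = 3, gc_min_diff = 0.02) {
  idx <- match(members, contigs$contig_id)
  if (anyNA(idx))
    stop("filter_outlier_contigs: missing stats for contig(s): ",
         paste(members[is.na(idx)], collapse = ", "))
  if (length(members) < 3)
    return(list(kept = members, removed = character(0),
                reasons = character(0)))
  sub <- contigs[idx, ]
  gc_med <- median(sub$gc)
  gc_mad <- mad(sub$gc)
  bad_gc <- abs(sub$gc - gc_med) > pmax(gc_mad_k * gc_mad, gc_min_diff)
  dep_med <- median(sub$depth)
  bad_dep <- sub$depth > dep_med * depth_fold | sub$depth < dep_med / depth_fold
  tet <- sub$tetra
  wmean <- colSums(tet * sub$length) / sum(sub$length)
  dist <- rowSums(abs(sweep(tet, 2, wmean)))
  bad_tet <- dist > quantile(dist, tetra_pct, names = FALSE) &
    dist > tetra_min_fold * median(dist)
  bad <- bad_gc | bad_dep | bad_tet
  reasons <- vapply(which(bad), function(i) {
    paste(c("gc", "depth", "tetra")[c(bad_gc[i], bad_dep[i], bad_tet[i])],
          collapse = ",")
  }, "")
  names(reasons) <- members[bad]
  list(kept = members[!bad], removed = members[bad], reasons = reasons)
}

#' Dereplicate bins by average amino-acid identity
#'
#' Builds the graph of bin pairs with AAI at or above `cutoff` and keeps,
#' within each connected component, the bin maximizing completeness (ties:
#' lower contamination, then bin id ascending). Component-wise resolution
#' makes the result independent of pair ordering.
#'
#' @param bins Bin table (columns `bin_id`, `completeness`,
#'   `contamination`).
#' @param aai Symmetric AAI matrix (percent) with bin ids as dimnames,
#'   covering all bins.
#' @param cutoff AAI threshold in percent (default 99, inclusive).
#' @return The kept subset of `bins`.
#' @export
dereplicate_by_aai <- function(bins, aai, cutoff = 99) {
  ids <- bins$bin_id
  if (!all(ids %in% rownames(aai)))
    stop("dereplicate_by_aai: AAI matrix does not cover all bins")
  a <- aai[ids, ids, drop = FALSE]
  n <- length(ids)
  comp <- seq_len(n)            # union-find over high-AAI pairs
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && a[i, j] >= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  keep <- unlist(lapply(split(seq_len(n), root), function(is) {
    is[order(-bins$completeness[is], bins$contamination[is],
             bins$bin_id[is])][1]
  }), use.names = FALSE)
  bins[sort(keep), , drop = FALSE]
}

#' Assign each contig to at most one bin
#'
#' A contig appearing in several bins stays in the bin with the higher
#' completeness (ties: lower contamination, then bin id ascending) and is
#' dropped from the rest. Idempotent.
#'
#' @param membership `data.frame(bin_id, contig_id)`.
#' @param bins Bin table with `bin_id`, `completeness`, `contamination`.
#' @return Deduplicated membership table.
#' @export
resolve_duplicate_contigs <- function(membership, bins) {
  pri <- order(-bins$completeness, bins$contamination, bins$bin_id)
  rank <- setNames(seq_along(pri), bins$bin_id[pri])
  ord <- order(rank[membership$bin_id])
  m <- membership[ord, ]
  m <- m[!duplicated(m$contig_id), ]
  m[order(m$bin_id, m$contig_id), , drop = FALSE]
}

#' Quality gate for MAGs
#'
#' Keeps bins with completeness at or above `min_completeness` and
#' contamination at or below `max_contamination` (boundaries inclusive).
#'
#' @param bins Bin table.
#' @param min_completeness,max_contamination Percent thresholds
#'   (defaults 70 and 9).
#' @return Qualified subset of `bins`.
#' @export
quality_gate <- function(bins, min_completeness = 70, max_contamination = 9) {
  bins[bins$completeness >= min_completeness &
         bins$contamination <= max_contamination, , drop = FALSE]
}

#' Relative abundance of MAGs
#'
#' Each bin's share of the community is the length-weighted depth of its
#' member contigs over the length-weighted depth of all contigs at or above
#' `min_len` (default 3 kb, the binning length cutoff). The remainder to 1
#' is the unbinned fraction.
#'
#' @param membership `data.frame(bin_id, contig_id)`.
#' @param contigs Contig table with `contig_id`, `length`, `depth`.
#' @param min_len Minimum contig length in bp (default 3000, inclusive).
#' @return Named numeric vector of fractions (one per bin, summing to at
#'   most 1) with attribute `unbinned`.
#' @export
mag_relative_abundance <- function(membership, contigs, min_len = 3000) {
  ok <- contigs$length >= min_len
  denom <- sum(contigs$depth[ok] * contigs$length[ok])
  if (denom <= 0) stop("mag_relative_abundance: no contig at or above min_len")
  w <- setNames(contigs$depth * contigs$length, contigs$contig_id)
  w[!ok] <- 0
  num <- tapply(w[membership$contig_id], membership$bin_id, sum)
  frac <- setNames(as.numeric(num) / denom, names(num))
  structure(frac, unbinned = 1 - sum(frac))
}

#' Is a MAG eligible for replication-rate estimation?
#'
#' Bacterial MAGs with at most 175 scaffolds per Mb qualify (boundary
#' inclusive); fragmentation beyond that makes the coverage trend
#' unreliable.
#'
#' @param scaffold_count Number of scaffolds.
#' @param total_length Total bin length in bp (> 0).
#' @param domain Taxonomic domain label; only `"Bacteria"` qualifies.
#' @param max_per_mb Threshold (default 175).
#' @return Logical.
#' @export
irep_eligible <- function(scaffold_count, total_length, domain = "Bacteria",
                          max_per_mb = 175) {
  stopifnot(total_length > 0)
  domain == "Bacteria" & scaffold_count / (total_length / 1e6) <= max_per_mb
}

#' Full MAG refinement workflow
#'
#' Outlier-contig filtering per bin, AAI dereplication, duplicate-contig
#' resolution, then the completeness/contamination quality gate. Bin
#' completeness/contamination values are marker-set estimates consumed as
#' input and are not recomputed after contig removal. The output is checked
#' to contain no duplicate contigs, no kept pair at or above the AAI
#' cutoff, and only gate-passing bins; the workflow is idempotent.
#'
#' @param bins Bin table (`bin_id`, `completeness`, `contamination`,
#'   `taxon` optional).
#' @param membership `data.frame(bin_id, contig_id)`.
#' @param contigs Contig stats table (see [filter_outlier_contigs()]).
#' @param aai AAI matrix over the bins.
#' @param gc_mad_k,depth_fold,tetra_pct Outlier thresholds.
#' @param aai_cutoff AAI dereplication threshold (percent).
#' @param min_completeness,max_contamination Quality gate thresholds.
#' @return List (class `mag_refinement`): `bins`, `membership`,
#'   `removed_contigs` (with reasons), `params`.
#' @export
refine_bins <- function(bins, membership, contigs, aai,
                        gc_mad_k = 3, depth_fold = 3, tetra_pct = 0.98,
                        aai_cutoff = 99,
                        min_completeness = 70, max_contamination = 9) {
  removed <- data.frame(bin_id = character(0), contig_id = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  kept_m <- list()
  for (b in unique(membership$bin_id)) {
    mem <- membership$contig_id[membership$bin_id == b]
    fl <- filter_outlier_contigs(mem, contigs, gc_mad_k, depth_fold,
                                 tetra_pct)
    if (length(fl$removed))
      removed <- rbind(removed, data.frame(
        bin_id = b, contig_id = fl$removed, reason = fl$reasons,
        stringsAsFactors = FALSE))
    kept_m[[b]] <- data.frame(bin_id = b, contig_id = fl$kept,
                              stringsAsFactors = FALSE)
  }
  membership <- do.call(rbind, kept_m)
  rownames(membership) <- NULL
  bins <- dereplicate_by_aai(bins, aai, aai_cutoff)
  membership <- membership[membership$bin_id %in% bins$bin_id, ]
  membership <- resolve_duplicate_contigs(membership, bins)
  bins <- quality_gate(bins, min_completeness, max_contamination)
  membership <- membership[membership$bin_id %in% bins$bin_id, ]
  bins <- bins[bins$bin_id %in% membership$bin_id, , drop = FALSE]
  rownames(bins) <- rownames(membership) <- NULL
  stopifnot(!anyDuplicated(membership$contig_id))
  ids <- bins$bin_id
  if (length(ids) > 1) {
    sub <- aai[ids, ids]
    stopifnot(all(sub[upper.tri(sub)] < aai_cutoff))
  }
  structure(list(bins = bins, membership = membership,
                 removed_contigs = removed,
                 params = list(gc_mad_k = gc_mad_k, depth_fold = depth_fold,
                               tetra_pct = tetra_pct,
                               aai_cutoff = aai_cutoff,
                               min_completeness = min_completeness,
                               max_contamination = max_contamination,
                               merge_thresholds = "percentage points")),
            class = "mag_refinement")
}

#' @export
print.mag_refinement <- function(x, ...) {
  cat(sprintf(paste0("MAG refinement: %d qualified bins, %d contigs ",
                     "removed as outliers\n"),
              nrow(x$bins), nrow(x$removed_contigs)))
  invisible(x)
}
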