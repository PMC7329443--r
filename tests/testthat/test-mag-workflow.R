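test_that("contig stats compute GC and collapsed tetranucleotides", {
  at <- compute_contig_stats("ATATATAT")
  expect_equal(at$gc, 0)
  expect_equal(sum(at$tetra), 1, tolerance = 1e-12)

  gc <- compute_contig_stats("GCGCGCGC")
  expect_equal(gc$gc, 1)
  # sliding windows: GCGC x3, CGCG x2; both palindromic classes
  expect_equal(unname(gc$tetra["CGCG"]), 2 / 5)
  expect_equal(unname(gc$tetra["GCGC"]), 3 / 5)
  expect_equal(sum(gc$tetra > 0), 2)

  # reverse-complement invariance of the collapsed vector
  s <- "ACGGTTACGATCGGATTACCGGTAGGCCTAAGCTT"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(compute_contig_stats(s)$tetra,
               compute_contig_stats(rc)$tetra)

  # N windows skipped, lowercase accepted
  expect_equal(compute_contig_stats("acgt")$gc, 0.5)
  n_in <- compute_contig_stats("ACGTNACGT")
  expect_equal(sum(n_in$tetra) , 1)
  expect_error(compute_contig_stats("ACG"), "shorter")
  expect_equal(length(canonical_tetramers()), 136)
})

test_that("merge rule needs same taxon, +10 completeness, <=1 contamination", {
  expect_true(merge_decision(c(55, 3), c(40, 2), c(68, 3.8), "A", "A"))
  expect_false(merge_decision(c(55, 3), c(40, 2), c(68, 4.5), "A", "A"))
  expect_false(merge_decision(c(55, 3), c(40, 2), c(64.9, 3), "A", "A"))
  expect_false(merge_decision(c(55, 3), c(40, 2), c(90, 0), "A", "B"))
  # boundaries inclusive: exactly +10 and exactly +1 accept
  expect_true(merge_decision(c(55, 3), c(40, 2), c(65, 4), "A", "A"))
})

test_that("outlier filtering removes divergent contigs with reasons", {
  sp <- mk_mag_community()
  meta <- generate_bin_metadata(sp, n_contigs = 25,
                                contamination_fraction = 0)
  b1 <- meta$membership$contig_id[meta$membership$bin_id == "bin001"]

  homog <- filter_outlier_contigs(b1, meta$contigs)
  expect_length(homog$removed, 0)

  # a 10x depth contig is removed for depth at depth_fold = 3
  ctg <- meta$contigs
  i <- match(b1[1], ctg$contig_id)
  ctg$depth[i] <- ctg$depth[i] * 10
  dep <- filter_outlier_contigs(b1, ctg)
  expect_true(b1[1] %in% dep$removed)
  expect_match(dep$reasons[[b1[1]]], "depth")

  # fewer than 3 contigs: no filtering
  expect_length(filter_outlier_contigs(b1[1:2], meta$contigs)$removed, 0)
  expect_error(filter_outlier_contigs(c(b1, "ghost"), meta$contigs),
               "missing stats")
})

test_that("injected contaminants are caught at >= 90% with <= 5% false removal", {
  sp <- mk_mag_community()
  meta <- generate_bin_metadata(sp, n_contigs = 30,
                                contamination_fraction = 0.2)
  ref <- refine_bins(meta$bins, meta$membership, meta$contigs, meta$aai)
  cont <- meta$truth$contaminants$contig_id
  removed <- ref$removed_contigs$contig_id
  native <- setdiff(meta$membership$contig_id, cont)
  expect_gte(mean(cont %in% removed), 0.90)
  expect_lte(mean(native %in% removed), 0.05)
})

test_that("AAI dereplication keeps the best bin per component", {
  bins <- data.frame(bin_id = c("b1", "b2"),
                     completeness = c(85, 78), contamination = c(2, 1))
  aai <- matrix(c(100, 99.4, 99.4, 100), 2,
                dimnames = list(bins$bin_id, bins$bin_id))
  expect_equal(dereplicate_by_aai(bins, aai)$bin_id, "b1")

  # all below cutoff: identity
  aai_lo <- matrix(c(100, 95, 95, 100), 2,
                   dimnames = list(bins$bin_id, bins$bin_id))
  expect_equal(dereplicate_by_aai(bins, aai_lo)$bin_id, c("b1", "b2"))

  # chain A-B (99.2), B-C (99.1), A-C (98.5): one connected component
  b3 <- data.frame(bin_id = c("a", "b", "c"),
                   completeness = c(80, 90, 85), contamination = c(1, 1, 1))
  m3 <- matrix(100, 3, 3, dimnames = list(b3$bin_id, b3$bin_id))
  m3["a", "b"] <- m3["b", "a"] <- 99.2
  m3["b", "c"] <- m3["c", "b"] <- 99.1
  m3["a", "c"] <- m3["c", "a"] <- 98.5
  kept <- dereplicate_by_aai(b3, m3)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$bin_id, "b")
  expect_error(dereplicate_by_aai(b3, m3[1:2, 1:2]), "cover")
})

test_that("duplicate contigs resolve to the better bin, idempotently", {
  bins <- data.frame(bin_id = c("hi", "lo"),
                     completeness = c(90, 70), contamination = c(1, 1))
  mem <- data.frame(bin_id = c("hi", "lo", "lo"),
                    contig_id = c("c1", "c1", "c2"))
  once <- resolve_duplicate_contigs(mem, bins)
  expect_equal(once$bin_id[once$contig_id == "c1"], "hi")
  expect_equal(nrow(once), 2)
  expect_equal(resolve_duplicate_contigs(once, bins), once)
  # no duplicates: identity (up to ordering)
  clean <- data.frame(bin_id = c("hi", "lo"), contig_id = c("c1", "c2"))
  expect_equal(resolve_duplicate_contigs(clean, bins), clean)
})

test_that("quality gate boundaries are inclusive", {
  bins <- data.frame(bin_id = c("a", "b", "c"),
                     completeness = c(70.0, 69.9, 100),
                     contamination = c(9.0, 0, 9.1))
  expect_equal(quality_gate(bins)$bin_id, "a")
})

test_that("MAG relative abundance is the length-weighted depth share", {
  ctg <- data.frame(contig_id = c("c1", "c2", "c3"),
                    length = c(1e4, 1e4, 2e4), depth = c(10, 30, 10))
  mem <- data.frame(bin_id = "b1", contig_id = c("c1", "c2"))
  fr <- mag_relative_abundance(mem, ctg)
  expect_equal(unname(fr["b1"]), 2 / 3)
  expect_equal(attr(fr, "unbinned"), 1 / 3)

  all_in <- data.frame(bin_id = "b1", contig_id = ctg$contig_id)
  expect_equal(unname(mag_relative_abundance(all_in, ctg)["b1"]), 1)

  # short contigs excluded from numerator and denominator
  ctg2 <- rbind(ctg, data.frame(contig_id = "tiny", length = 2000,
                                depth = 1000))
  mem2 <- rbind(mem, data.frame(bin_id = "b1", contig_id = "tiny"))
  expect_equal(unname(mag_relative_abundance(mem2, ctg2)["b1"]), 2 / 3)
  expect_error(mag_relative_abundance(mem, ctg, min_len = 1e6), "min_len")
})

test_that("iRep eligibility uses scaffolds per Mb with inclusive boundary", {
  expect_true(irep_eligible(100, 1e6))
  expect_false(irep_eligible(200, 1e6))
  expect_true(irep_eligible(350, 2e6))
  expect_false(irep_eligible(100, 1e6, domain = "Archaea"))
})

test_that("the refinement workflow is idempotent and self-consistent", {
  sp <- mk_mag_community()
  meta <- generate_bin_metadata(sp, n_contigs = 25,
                                contamination_fraction = 0.15,
                                duplicate_bins = 1)
  ref <- refine_bins(meta$bins, meta$membership, meta$contigs, meta$aai)
  expect_false(any(duplicated(ref$membership$contig_id)))
  expect_true(all(ref$bins$completeness >= 70 & ref$bins$contamination <= 9))
  ids <- ref$bins$bin_id
  if (length(ids) > 1)
    expect_true(all(meta$aai[ids, ids][upper.tri(diag(length(ids)))] < 99))
  # truth completeness of retained bins clears the gate
  truth <- meta$truth$bins
  expect_true(all(truth$completeness[match(ids, truth$bin_id)] >= 70))

  again <- refine_bins(ref$bins, ref$membership, meta$contigs, meta$aai)
  expect_equal(again$bins, ref$bins)
  expect_equal(again$membership, ref$membership)
  expect_equal(nrow(again$removed_contigs), 0)
})
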