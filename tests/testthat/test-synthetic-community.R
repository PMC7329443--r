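test_that("gene tables allocate reads multinomially and deterministically", {
  one <- community_spec(list(mk_taxon("solo", genes = data.frame(
    symbol = "soxB", length = 1000))), total_reads = 1000, seed = 5)
  g <- generate_gene_table(one, "S")
  expect_equal(g$reads, 1000)

  two <- community_spec(list(mk_taxon("solo", genes = data.frame(
    symbol = c("a", "b"), length = c(1000, 1000)))),
    total_reads = 1e6, seed = 5)
  g2 <- generate_gene_table(two, "S")
  expect_equal(sum(g2$reads), 1e6)
  sd_binom <- sqrt(1e6 * 0.5 * 0.5)
  expect_true(all(abs(g2$reads - 5e5) < 5 * sd_binom))

  expect_identical(generate_gene_table(two, "S"),
                   generate_gene_table(two, "S"))

  bad <- list(mk_taxon("z", weight = 0))
  expect_error(community_spec(bad), "weights")
})

test_that("read totals are conserved across taxa and samples", {
  sp <- mk_mag_community()
  for (s in c("A", "B")) {
    g <- generate_gene_table(sp, s)
    expect_equal(sum(g$reads), sp$total_reads)
  }
})

test_that("coverage tracks carry the 1 + f_rep replication gradient", {
  flat <- generate_coverage_track(5e5, 30, 0, seed = 3)
  k <- nrow(flat)
  expect_true(abs(mean(flat$depth) - 30) < 3 * sqrt(30 / k))

  exact <- generate_coverage_track(1e6, 20, 1, noise = FALSE)
  expect_equal(exact$depth[1] / exact$depth[nrow(exact)], 2.0)

  half <- generate_coverage_track(1e6, 20, 0.5, noise = FALSE)
  expect_equal(half$depth[1] / half$depth[nrow(half)], 1.5)

  expect_error(generate_coverage_track(1e6, 20, 1.2), "f_rep")
})

test_that("coverage-track slope reproduces 1 + f_rep over replicates", {
  # Monte-Carlo: terminus->origin depth ratio across 50 seeded replicates
  ratios <- vapply(1:50, function(s) {
    tr <- generate_coverage_track(2e5, 40, 0.6, seed = s)
    n <- nrow(tr)
    head_mean <- mean(tr$depth[1:50])
    tail_mean <- mean(tr$depth[(n - 49):n])
    head_mean / tail_mean
  }, 0)
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_true(abs(mean(ratios) - 1.6) < 3 * se + 0.02)
})

test_that("fluid samples sit on the conservative mixing line", {
  sw <- c(Mg = 53, c = 2)
  em <- c(c = 10)
  pure_sw <- fluid_mix_spec(em, sw, phi = 1, noise_sd = 0)
  expect_equal(unname(unlist(
    generate_fluid_samples(pure_sw)[, c("Mg", "c")])), c(53, 2))

  pure_em <- fluid_mix_spec(em, sw, phi = 0, noise_sd = 0)
  expect_equal(unname(unlist(
    generate_fluid_samples(pure_em)[, c("Mg", "c")])), c(0, 10))

  mix <- fluid_mix_spec(em, sw, phi = c(20 / 53, 40 / 53), noise_sd = 0)
  fl <- generate_fluid_samples(mix)
  expect_equal(fl$Mg, c(20, 40))
  expect_equal(fl$c, c(10 - 8 * 20 / 53, 10 - 8 * 40 / 53), tolerance = 1e-9)
  expect_equal(round(fl$c, 3), c(6.981, 3.962))

  # noise-free points are exactly collinear in (Mg, concentration)
  mix3 <- fluid_mix_spec(em, sw, phi = c(0.1, 0.4, 0.9), noise_sd = 0)
  f3 <- generate_fluid_samples(mix3)
  slopes <- diff(f3$c) / diff(f3$Mg)
  expect_equal(slopes[1], slopes[2], tolerance = 1e-12)

  noisy <- fluid_mix_spec(c(c = 0.001), sw, phi = rep(0.01, 20),
                          noise_sd = 0.5, seed = 2)
  expect_message(generate_fluid_samples(noisy), "clipped")
})

test_that("bin metadata reports truthful quality and block-structured AAI", {
  sp <- mk_mag_community()
  clean <- generate_bin_metadata(sp, n_contigs = 10,
                                 contamination_fraction = 0)
  expect_true(all(clean$bins$contamination == 0))
  full <- generate_bin_metadata(sp, n_contigs = 10, completeness = 1,
                                contamination_fraction = 0)
  expect_true(all(full$bins$completeness == 100))

  meta <- generate_bin_metadata(sp, n_contigs = 20,
                                contamination_fraction = 0.15,
                                duplicate_bins = 1)
  expect_identical(meta,
                   generate_bin_metadata(sp, n_contigs = 20,
                                         contamination_fraction = 0.15,
                                         duplicate_bins = 1))
  aai <- meta$aai
  expect_equal(unname(diag(aai)), rep(100, nrow(aai)))
  expect_equal(aai, t(aai))
  same <- outer(meta$bins$taxon, meta$bins$taxon, "==") &
    !diag(nrow(aai))
  expect_true(all(aai[same] >= 99))
  expect_true(all(aai[!same & !diag(nrow(aai))] < 95))
  # every contig in a bin has stats; contaminants carry their source taxon
  expect_true(all(meta$membership$contig_id %in% meta$contigs$contig_id))
  cont <- meta$truth$contaminants
  src <- meta$contigs$taxon[match(cont$contig_id, meta$contigs$contig_id)]
  own <- meta$bins$taxon[match(cont$bin_id, meta$bins$bin_id)]
  expect_true(all(src != own))
})

test_that("community files round-trip through the writers", {
  sp <- mk_mag_community()
  dir <- withr::local_tempdir()
  paths <- write_community_files(sp, dir, samples = "A",
                                 mix = fluid_mix_spec(
                                   c(H2S = 6.3), seawater_reference(),
                                   phi = c(0.2, 0.6), noise_sd = 0))
  expect_true(all(file.exists(paths)))
  g <- read_gene_table(paths[["genes_A"]])
  expect_equal(sum(g$reads), sp$total_reads)
  ctg <- read_contig_table(paths[["contigs"]])
  expect_true(is.matrix(ctg$tetra))
  expect_equal(rowSums(ctg$tetra), setNames(rep(1, nrow(ctg)),
                                            ctg$contig_id),
               tolerance = 1e-9)
  cov <- read_bedgraph(paths[["coverage"]])
  expect_s3_class(cov, "coverage_track")
  expect_equal(attr(cov, "cell"), 100)
})
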