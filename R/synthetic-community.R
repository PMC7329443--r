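#' Describe one taxon of a synthetic community
#'
#' A taxon is the unit of the generator: it carries a relative-abundance
#' weight, a gene catalog (symbols and lengths) used for read simulation,
#' a pathway gene content, and a replicating fraction `f_rep` controlling
#' the origin-to-terminus coverage gradient of its genome.
#'
#' @param name Taxon name (unique within a community).
#' @param phylum Phylum-level label (class level works too; it is only a
#'   grouping label).
#' @param weight Relative abundance weight (>= 0).
#' @param genome_length Genome length in bp.
#' @param genes `data.frame` with columns `symbol` and `length` (bp). A gene
#'   catalog may repeat a symbol (paralogs).
#' @param pathway_genes Character vector of gene symbols present in the
#'   genome for pathway-completeness calling (defaults to `genes$symbol`).
#' @param f_rep Fraction of cells carrying one replication fork, in [0, 1].
#' @param gc Genomic GC content in [0, 1] (used for contig metadata).
#' @param depth Mean sequencing depth (x-fold) of the genome, used for
#'   contig and coverage metadata.
#' @return A `taxon_spec` list.
#' @export
taxon_spec <- function(name, phylum, weight, genome_length,
                       genes, pathway_genes = NULL,
                       f_rep = 0, gc = 0.5, depth = 30) {
  stopifnot(is.character(name), length(name) == 1L,
            weight >= 0, genome_length > 0,
            is.data.frame(genes), all(c("symbol", "length") %in% names(genes)),
            all(genes$length > 0),
            f_rep >= 0, f_rep <= 1, gc >= 0, gc <= 1, depth > 0)
  structure(list(
    name = name, phylum = phylum, weight = weight,
    genome_length = genome_length, genes = genes,
    pathway_genes = pathway_genes %||% unique(genes$symbol),
    f_rep = f_rep, gc = gc, depth = depth
  ), class = "taxon_spec")
}

#' Specify a synthetic microbial community
#'
#' The community spec fixes the statistical structure every generator draws
#' from: multinomial read allocation proportional to taxon weight times gene
#' length, Poisson depth noise, and optional lognormal between-sample
#' dispersion of taxon abundances.
#'
#' @param taxa List of [taxon_spec()] objects; at least one weight must be
#'   positive.
#' @param read_length Read length in bp (default 100, a 2 x 100 bp
#'   short-read design).
#' @param total_reads Reads mapped per sample.
#' @param abundance_sdlog Lognormal sd of per-sample taxon abundance
#'   dispersion (0 = none).
#' @param seed Integer seed; every generator is deterministic given it.
#' @return A `community_spec` list.
#' @export
community_spec <- function(taxa, read_length = 100, total_reads = 1e6,
                           abundance_sdlog = 0, seed = 42) {
  stopifnot(length(taxa) >= 1, all(vapply(taxa, inherits, TRUE, "taxon_spec")))
  w <- vapply(taxa, `[[`, 0, "weight")
  if (all(w <= 0)) stop("community_spec: all taxon weights are zero")
  nm <- vapply(taxa, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("community_spec: duplicate taxon names")
  structure(list(
    taxa = taxa, read_length = read_length, total_reads = total_reads,
    abundance_sdlog = abundance_sdlog, seed = seed
  ), class = "community_spec")
}

#' Simulate an annotated gene table for one sample
#'
#' Reads are allocated to genes by a single multinomial draw with
#' probability proportional to taxon weight x gene length; per-gene depth is
#' `reads * read_length / length`. With `abundance_sdlog > 0` each taxon's
#' weight is first jittered lognormally (mean-preserving), emulating
#' between-sample compositional noise.
#'
#' @param spec A [community_spec()].
#' @param sample_id Sample label attached to the table.
#' @param seed Seed override; defaults to `spec$seed` combined with the
#'   sample id so two samples differ but each is reproducible.
#' @return `data.frame` with columns `gene_id`, `contig_id`, `symbol`,
#'   `length`, `taxon`, `phylum`, `reads`, `depth` and attribute
#'   `read_length`.
#' @export
generate_gene_table <- function(spec, sample_id = "S1", seed = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  seed <- seed %||% (spec$seed + sum(utf8ToInt(sample_id)))
  tab <- do.call(rbind, lapply(spec$taxa, function(tx) {
    data.frame(
      symbol = tx$genes$symbol, length = tx$genes$length,
      taxon = tx$name, phylum = tx$phylum, weight = tx$weight,
      stringsAsFactors = FALSE
    )
  }))
  tab$gene_id <- sprintf("%s_g%04d", tab$taxon, stats::ave(
    seq_len(nrow(tab)), tab$taxon, FUN = seq_along))
  tab$contig_id <- paste0(tab$taxon, "_c1")
  with_seed(seed, {
    w <- tab$weight
    if (spec$abundance_sdlog > 0) {
      jit <- exp(rnorm(length(spec$taxa), -spec$abundance_sdlog^2 / 2,
                       spec$abundance_sdlog))
      w <- w * jit[match(tab$taxon, vapply(spec$taxa, `[[`, "", "name"))]
    }
    prob <- w * tab$length
    tab$reads <- as.vector(rmultinom(1, spec$total_reads, prob))
  })
  tab$depth <- tab$reads * spec$read_length / tab$length
  out <- tab[, c("gene_id", "contig_id", "symbol", "length", "taxon",
                 "phylum", "reads", "depth")]
  attr(out, "read_length") <- spec$read_length
  attr(out, "sample_id") <- sample_id
  out
}

#' Simulate a coverage track with a replication gradient
#'
#' Models a population in which a fraction `f_rep` of cells carry a single
#' replication fork at a uniformly random genome position: expected copy
#' number at origin-distance fraction `x` is `1 + f_rep * (1 - x)`, so the
#' expected origin:terminus depth ratio is `1 + f_rep`. Window depths are
#' Poisson about `mean_depth` times copy number (or exact with
#' `noise = FALSE`).
#'
#' @param genome_len Genome length, bp.
#' @param mean_depth Depth at the terminus (x-fold), > 0.
#' @param f_rep Replicating fraction in [0, 1].
#' @param window Track cell size in bp (default 100, the read length).
#' @param seed Integer seed (ignored when `noise = FALSE`).
#' @param noise Poisson window noise on/off.
#' @param n_contigs Split the genome into this many contigs.
#' @param shuffle Shuffle contig order relative to origin distance (the
#'   downstream estimator sorts by depth, so it must not rely on input
#'   order).
#' @return A `coverage_track`: `data.frame(contig, start, end, depth)` with
#'   0-based half-open intervals and attribute `cell` (bp).
#' @export
generate_coverage_track <- function(genome_len, mean_depth, f_rep,
                                    window = 100, seed = 1, noise = TRUE,
                                    n_contigs = 1, shuffle = FALSE) {
  stopifnot(f_rep >= 0, f_rep <= 1, mean_depth > 0,
            genome_len >= 10 * window, n_contigs >= 1)
  k <- floor(genome_len / window)
  x <- if (k > 1) (seq_len(k) - 1) / (k - 1) else 0
  lambda <- mean_depth * (1 + f_rep * (1 - x))
  depth <- if (noise) with_seed(seed, rpois(k, lambda)) else lambda
  contig_of <- sort(rep_len(seq_len(n_contigs), k))
  if (shuffle && n_contigs > 1) {
    ord <- with_seed(seed + 1L, sample.int(n_contigs))
    idx <- order(match(contig_of, ord))
    depth <- depth[idx]
    contig_of <- contig_of[idx]
  }
  off <- stats::ave(seq_along(contig_of), contig_of, FUN = seq_along) - 1L
  out <- data.frame(
    contig = sprintf("ctg%03d", contig_of),
    start = off * window,
    end = (off + 1L) * window,
    depth = depth,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("coverage_track", "data.frame"), cell = window)
}

#' Specify conservative mixing of endmember fluid and seawater
#'
#' @param endmember Named numeric vector of endmember concentrations. `Mg`
#'   is forced to exactly 0 (the defining property of the endmember).
#' @param seawater Named numeric vector of seawater concentrations; must
#'   contain `Mg` (~53 mmol/kg in ambient seawater).
#' @param phi Seawater mixing fractions in [0, 1], one synthetic sample per
#'   value.
#' @param noise_sd Measurement noise sd; scalar or named per species.
#' @param seed Integer seed.
#' @return A `fluid_mix_spec` list.
#' @export
fluid_mix_spec <- function(endmember, seawater, phi, noise_sd = 0, seed = 42) {
  stopifnot(!is.null(names(endmember)), !is.null(names(seawater)),
            "Mg" %in% names(seawater), all(phi >= 0), all(phi <= 1))
  endmember["Mg"] <- 0
  species <- union(names(seawater), names(endmember))
  em <- setNames(ifelse(species %in% names(endmember),
                        endmember[species], 0), species)
  sw <- setNames(ifelse(species %in% names(seawater),
                        seawater[species], 0), species)
  sd <- if (length(noise_sd) == 1L) setNames(rep(noise_sd, length(species)),
                                             species) else noise_sd[species]
  sd[is.na(sd)] <- 0
  structure(list(endmember = em, seawater = sw, phi = phi,
                 noise_sd = sd, seed = seed),
            class = "fluid_mix_spec")
}

#' Simulate vent-fluid samples on a conservative mixing line
#'
#' Each sample is `phi * seawater + (1 - phi) * endmember` plus Gaussian
#' measurement noise; Mg tracks the seawater fraction since the endmember is
#' Mg-free. Negative generated concentrations are clipped to 0 with a
#' message.
#'
#' @param mix A [fluid_mix_spec()].
#' @return `data.frame` with `sample_id`, `phi`, and one column per species
#'   (including `Mg`).
#' @export
generate_fluid_samples <- function(mix) {
  stopifnot(inherits(mix, "fluid_mix_spec"))
  species <- names(mix$seawater)
  out <- with_seed(mix$seed, {
    rows <- lapply(seq_along(mix$phi), function(i) {
      phi <- mix$phi[i]
      conc <- phi * mix$seawater + (1 - phi) * mix$endmember +
        rnorm(length(species), 0, mix$noise_sd)
      conc
    })
    do.call(rbind, rows)
  })
  neg <- out < 0
  if (any(neg)) {
    message(sprintf("generate_fluid_samples: clipped %d negative value(s) to 0",
                    sum(neg)))
    out[neg] <- 0
  }
  data.frame(sample_id = sprintf("IGT%02d", seq_along(mix$phi)),
             phi = mix$phi, out, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Simulate contig, bin and AAI metadata for a community
#'
#' Fragments each taxon's genome into contigs carrying taxon-specific GC,
#' depth and tetranucleotide signatures, assembles one candidate bin per
#' genome covering roughly `completeness` of its length, optionally injects
#' contaminant contigs drawn from other taxa (with their own true
#' signatures), and emits an AAI matrix in which same-taxon bin pairs score
#' >= 99% and different-taxon pairs < 95%.
#'
#' @param spec A [community_spec()].
#' @param n_contigs Contigs per genome.
#' @param completeness Target fraction of genome length placed in the bin.
#' @param contamination_fraction Contaminant contigs injected per bin, as a
#'   fraction of its native contig count.
#' @param duplicate_bins Number of taxa that additionally get a second,
#'   lower-completeness bin (exercises AAI dereplication and duplicate
#'   contig resolution).
#' @param gc_sd,depth_sdlog Within-genome contig-to-contig jitter of GC and
#'   depth.
#' @param seed Seed override; defaults to `spec$seed`.
#' @return List with elements `contigs` (stats table incl. a `tetra` matrix
#'   column), `bins`, `membership`, `aai`, and `truth` (per-bin truth
#'   completeness/contamination; per-contig source taxon and contaminant
#'   flag).
#' @export
generate_bin_metadata <- function(spec, n_contigs = 12, completeness = 0.95,
                                  contamination_fraction = 0,
                                  duplicate_bins = 0,
                                  gc_sd = 0.005, depth_sdlog = 0.05,
                                  seed = NULL) {
  stopifnot(inherits(spec, "community_spec"), n_contigs >= 2,
            completeness > 0, completeness <= 1)
  seed <- seed %||% spec$seed
  with_seed(seed, {
    kmers <- canonical_tetramers()
    taxa <- spec$taxa
    profiles <- lapply(taxa, function(tx) {
      # taxon-specific tetranucleotide profile: GC-consistent dirichlet-ish
      gcw <- vapply(strsplit(kmers, ""), function(ch)
        sum(ch %in% c("G", "C")), 0)
      w <- exp(gcw * log(tx$gc / (1 - tx$gc) + 1e-9) * 0.5) *
        rgamma_det(length(kmers))
      w / sum(w)
    })
    names(profiles) <- vapply(taxa, `[[`, "", "name")

    contig_rows <- list()
    draw_contig <- function(id, tx, len) {
      list(contig_id = id, taxon = tx$name, length = len,
           gc = min(1, max(0, rnorm(1, tx$gc, gc_sd))),
           depth = tx$depth * exp(rnorm(1, 0, depth_sdlog)),
           tetra = pmax(0, profiles[[tx$name]] +
                          rnorm(length(kmers), 0, 2e-4)))
    }
    for (ti in seq_along(taxa)) {
      tx <- taxa[[ti]]
      frac <- as.vector(rmultinom(1, 1000, rep(1, n_contigs))) / 1000
      len <- pmax(500L, as.integer(round(frac * tx$genome_length)))
      for (ci in seq_len(n_contigs)) {
        contig_rows[[length(contig_rows) + 1L]] <-
          draw_contig(sprintf("%s_c%02d", tx$name, ci), tx, len[ci])
      }
    }
    contigs <- data.frame(
      contig_id = vapply(contig_rows, `[[`, "", "contig_id"),
      taxon = vapply(contig_rows, `[[`, "", "taxon"),
      length = vapply(contig_rows, function(r) as.numeric(r$length), 0),
      gc = vapply(contig_rows, `[[`, 0, "gc"),
      depth = vapply(contig_rows, `[[`, 0, "depth"),
      stringsAsFactors = FALSE
    )
    tet <- do.call(rbind, lapply(contig_rows, `[[`, "tetra"))
    tet <- tet / rowSums(tet)
    colnames(tet) <- kmers
    rownames(tet) <- contigs$contig_id
    contigs$tetra <- tet

    tax_names <- vapply(taxa, `[[`, "", "name")
    bins <- list(); membership <- list()
    contaminant_rows <- list()
    contaminants <- data.frame(bin_id = character(0), contig_id = character(0),
                               stringsAsFactors = FALSE)
    bin_n <- 0L
    dup_taxa <- if (duplicate_bins > 0)
      tax_names[seq_len(min(duplicate_bins, length(tax_names)))] else character(0)
    for (ti in seq_along(tax_names)) {
      tx_name <- tax_names[ti]
      reps <- if (tx_name %in% dup_taxa) c(completeness, completeness * 0.8)
              else completeness
      for (r in reps) {
        bin_n <- bin_n + 1L
        bid <- sprintf("bin%03d", bin_n)
        own <- contigs$contig_id[contigs$taxon == tx_name]
        own_len <- contigs$length[match(own, contigs$contig_id)]
        ord <- sample(seq_along(own))
        keep <- ord[cumsum(own_len[ord]) / sum(own_len) <= r + 1e-9]
        if (!length(keep)) keep <- ord[1]
        members <- own[keep]
        native_len <- sum(own_len[keep])
        # contamination: fresh short foreign contigs with their source
        # taxon's true GC/depth/tetra signatures
        n_cont <- round(contamination_fraction * length(members))
        cont_len <- 0
        if (n_cont > 0 && length(taxa) > 1) {
          for (xi in seq_len(n_cont)) {
            src <- taxa[[sample(setdiff(seq_along(taxa), ti), 1)]]
            row <- draw_contig(sprintf("%s_x%02d", bid, xi), src,
                               round(runif(1, 3000, 15000)))
            contaminant_rows[[length(contaminant_rows) + 1L]] <- row
            contaminants <- rbind(contaminants, data.frame(
              bin_id = bid, contig_id = row$contig_id,
              stringsAsFactors = FALSE))
            members <- c(members, row$contig_id)
            cont_len <- cont_len + row$length
          }
        }
        genome_len <- sum(own_len)
        bins[[bid]] <- data.frame(
          bin_id = bid, taxon = tx_name,
          completeness = 100 * native_len / genome_len,
          contamination = 100 * cont_len / max(native_len, 1),
          total_length = native_len + cont_len,
          scaffold_count = length(members),
          domain = "Bacteria", stringsAsFactors = FALSE)
        membership[[bid]] <- data.frame(bin_id = bid, contig_id = members,
                                        stringsAsFactors = FALSE)
      }
    }
    bins <- do.call(rbind, bins); rownames(bins) <- NULL
    membership <- do.call(rbind, membership); rownames(membership) <- NULL
    if (length(contaminant_rows)) {
      extra <- data.frame(
        contig_id = vapply(contaminant_rows, `[[`, "", "contig_id"),
        taxon = vapply(contaminant_rows, `[[`, "", "taxon"),
        length = vapply(contaminant_rows, function(r) as.numeric(r$length), 0),
        gc = vapply(contaminant_rows, `[[`, 0, "gc"),
        depth = vapply(contaminant_rows, `[[`, 0, "depth"),
        stringsAsFactors = FALSE)
      xt <- do.call(rbind, lapply(contaminant_rows, `[[`, "tetra"))
      xt <- xt / rowSums(xt)
      colnames(xt) <- kmers
      rownames(xt) <- extra$contig_id
      extra$tetra <- xt
      contigs <- rbind(contigs, extra)
    }

    nb <- nrow(bins)
    aai <- matrix(0, nb, nb, dimnames = list(bins$bin_id, bins$bin_id))
    for (i in seq_len(nb)) for (j in seq_len(nb)) {
      if (i == j) aai[i, j] <- 100
      else if (i < j) {
        same <- bins$taxon[i] == bins$taxon[j]
        aai[i, j] <- aai[j, i] <-
          if (same) runif(1, 99, 99.9) else runif(1, 75, 94.9)
      }
    }
    truth <- list(
      bins = bins[, c("bin_id", "taxon", "completeness", "contamination")],
      contigs = data.frame(contig_id = contigs$contig_id,
                           taxon = contigs$taxon, stringsAsFactors = FALSE),
      contaminants = contaminants
    )
    list(contigs = contigs, bins = bins, membership = membership,
         aai = aai, truth = truth)
  })
}

# Deterministic-ish positive weights used to roughen tetra profiles;
# draws from the current (seeded) RNG stream.
rgamma_det <- function(n) stats::rgamma(n, shape = 2, rate = 2)

#' Write every synthetic input the pipeline consumes
#'
#' Emits `genes_<sample>.tsv`, `contigs.tsv`, `bins.tsv`, `membership.tsv`,
#' `aai.tsv`, `coverage.bedgraph`, `fluids.csv` and `truth.tsv` under `dir`.
#'
#' @param spec A [community_spec()].
#' @param dir Output directory (created if needed).
#' @param samples Sample ids for gene tables.
#' @param mix Optional [fluid_mix_spec()] for fluids.csv.
#' @param ... Passed to [generate_bin_metadata()].
#' @return Invisibly, the named vector of written paths.
#' @export
write_community_files <- function(spec, dir, samples = c("A", "B"),
                                  mix = NULL, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (s in samples) {
    p <- file.path(dir, sprintf("genes_%s.tsv", s))
    write_tsv(generate_gene_table(spec, s), p)
    paths[paste0("genes_", s)] <- p
  }
  meta <- generate_bin_metadata(spec, ...)
  ctg <- meta$contigs
  tet <- ctg$tetra
  ctg$tetra <- NULL
  flat <- cbind(ctg, as.data.frame(tet, check.names = FALSE))
  write_tsv(flat, paths["contigs"] <- file.path(dir, "contigs.tsv"))
  write_tsv(meta$bins, paths["bins"] <- file.path(dir, "bins.tsv"))
  write_tsv(meta$membership,
            paths["membership"] <- file.path(dir, "membership.tsv"))
  aai_df <- data.frame(bin_id = rownames(meta$aai), meta$aai,
                       check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(aai_df, paths["aai"] <- file.path(dir, "aai.tsv"))

  covs <- lapply(seq_along(spec$taxa), function(i) {
    tx <- spec$taxa[[i]]
    trk <- generate_coverage_track(tx$genome_length, tx$depth, tx$f_rep,
                                   seed = spec$seed + i)
    trk$contig <- paste0(tx$name, "_cov")
    trk
  })
  cov <- do.call(rbind, covs)
  write_bedgraph(cov, paths["coverage"] <- file.path(dir, "coverage.bedgraph"))

  if (!is.null(mix)) {
    fl <- generate_fluid_samples(mix)
    write.csv(fl, paths["fluids"] <- file.path(dir, "fluids.csv"),
              row.names = FALSE)
  }
  write_tsv(meta$truth$bins, paths["truth"] <- file.path(dir, "truth.tsv"))
  invisible(paths)
}
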