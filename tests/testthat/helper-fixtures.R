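# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; nothing is read from disk except the packaged
# synthetic L-vent fluid table.

mk_taxon <- function(name, gc = 0.45, depth = 40, weight = 1, f_rep = 0,
                     genome = 2e6, genes = NULL) {
  genes <- genes %||% data.frame(symbol = c("soxB", "rps3"),
                                 length = c(1200, 700))
  taxon_spec(name, paste0("Phylum_", name), weight, genome, genes,
             f_rep = f_rep, gc = gc, depth = depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Three-taxon community with distinct GC/depth signatures, used by the MAG
# workflow fixtures.
mk_mag_community <- function(seed = 11) {
  community_spec(list(
    mk_taxon("Sulfurovum", gc = 0.35, depth = 50, weight = 3),
    mk_taxon("Nitrospira", gc = 0.55, depth = 30, weight = 2),
    mk_taxon("Chloroflexi", gc = 0.45, depth = 80, weight = 1)
  ), total_reads = 1e5, seed = seed)
}

# Two gene tables forming the differential contrast of the end-to-end
# test: `n_enr` symbols are 10-fold enriched in sample A while every null
# symbol keeps the same expected proportion in both samples (a background
# gene pool absorbs the enrichment, so nulls are true nulls).
mk_contrast_tables <- function(seed, n_null = 27, n_enr = 3,
                               total_reads = 2e5) {
  sym <- sprintf("s%02d", seq_len(n_null + n_enr))
  enriched <- sym[seq_len(n_enr)]
  one_gene <- function(s) data.frame(symbol = s, length = 1000)
  # A background gene pool absorbs the enrichment so both samples have the
  # same total weight (n_null + n_enr + 60): null symbols keep identical
  # expected proportions in A and B, enriched ones differ 10-fold.
  bg_a <- (n_null + n_enr + 60) - (10 * n_enr + n_null)
  stopifnot(bg_a > 0)
  mk_side <- function(enr_weight, bg_weight) c(
    lapply(sym, function(s) mk_taxon(paste0("T", s),
      weight = if (s %in% enriched) enr_weight else 1, genes = one_gene(s))),
    list(mk_taxon("Tbg", weight = bg_weight, genes = one_gene("background"))))
  spec_a <- community_spec(mk_side(10, bg_a), total_reads = total_reads,
                           seed = seed)
  spec_b <- community_spec(mk_side(1, 60), total_reads = total_reads,
                           seed = seed + 1000L)
  list(a = generate_gene_table(spec_a, "A"),
       b = generate_gene_table(spec_b, "B"),
       enriched = enriched,
       null = setdiff(sym, enriched))
}

# Independent brute-force oracle for the two-sided Fisher p-value:
# enumerate all tables with the observed margins via binomial-coefficient
# ratios (no dhyper).
fisher_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  m <- a + c
  k <- a + b
  supp <- max(0, k - (N - m)):min(k, m)
  pr <- choose(m, supp) * choose(N - m, k - supp) / choose(N, k)
  obs <- choose(m, a) * choose(N - m, k - a) / choose(N, k)
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Step-up BH oracle written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}

# Hand-coded per-pathway completeness oracles, independent of the rule
# engine (plain if/else over symbol membership).
pathway_oracles <- function() {
  grade <- function(n) c("none", "partial", "uncomplete", "complete")[n + 1]
  list(
    sulfide_oxidation = function(s)
      if (any(c("sqr", "fccB") %in% s)) "complete" else "none",
    sox = function(s) {
      if (all(c("soxA", "soxB", "soxX", "soxY", "soxZ", "soxC",
                "soxD") %in% s)) "complete"
      else if ("soxB" %in% s) "uncomplete"
      else if (any(c("soxA", "soxX", "soxY", "soxZ") %in% s)) "partial"
      else "none"
    },
    dsr = function(s)
      grade(("sat" %in% s) + all(c("dsrA", "dsrB") %in% s) +
              all(c("aprA", "aprB") %in% s)),
    dnra = function(s) {
      if ("nirB" %in% s || all(c("nrfA", "nrfH") %in% s)) "complete"
      else if (any(c("nrfA", "nrfH") %in% s)) "uncomplete"
      else "none"
    },
    denitrification = function(s)
      grade(any(c("nirS", "nirK") %in% s) + any(c("norB", "norC") %in% s) +
              ("nosZ" %in% s)),
    nitrogen_fixation = function(s)
      grade(sum(c("nifK", "nifD", "nifH") %in% s)),
    wood_ljungdahl = function(s) {
      head_ok <- any(c("cdhC", "acsB") %in% s)
      if (head_ok && all(c("cdhE", "cdhD", "cooS") %in% s)) "complete"
      else if (head_ok && any(c("cdhE", "cdhD") %in% s) && "cooS" %in% s)
        "uncomplete"
      else if (any(c("cdhC", "cdhB") %in% s) + any(c("cdhE", "cdhD") %in% s) +
                 ("cooS" %in% s) >= 2) "partial"
      else "none"
    },
    co_oxidation = function(s) {
      if (all(c("coxM", "coxL", "coxS") %in% s)) "complete"
      else if ("coxL" %in% s && any(c("coxS", "coxM") %in% s)) "uncomplete"
      else if (any(c("coxM", "coxL", "coxS") %in% s)) "partial"
      else "none"
    },
    acetate_metabolism = function(s)
      if ("ACSS" %in% s || all(c("pta", "ack") %in% s)) "complete"
      else "none",
    rtca = function(s) {
      if (all(c("aclA", "aclB") %in% s)) "complete"
      else if (any(c("aclA", "aclB") %in% s)) "uncomplete"
      else "none"
    },
    cbb = function(s) {
      if (all(c("rbcL", "rbcS") %in% s)) "complete"
      else if (any(c("rbcL", "rbcS") %in% s)) "uncomplete"
      else "none"
    },
    methanogenesis = function(s)
      grade(if (all(c("mcrA", "mcrG", "mcrB") %in% s)) 3
            else sum(c("mcrA", "mcrG", "mcrB") %in% s)),
    cytochrome_c_oxidase = function(s) {
      hi <- sum(c("coxA", "coxB", "cydA", "cydB", "qoxA", "qoxB") %in% s)
      lo <- sum(c("ccoN", "ccoO", "ccoP", "cyoA", "cyoB", "cyoC") %in% s)
      if (hi >= 2 || lo >= 3) "complete"
      else if (hi >= 1 || lo >= 2) "uncomplete"
      else if (lo >= 1) "partial"
      else "none"
    },
    cyc2 = function(s) if ("cyc2" %in% s) "present" else "absent",
    fermentation = function(s)
      if (any(c("pflB", "ldh", "adhE", "porA") %in% s)) "present"
      else "absent"
  )
}

level_rank <- function(lvl) {
  c(none = 0, absent = 0, partial = 1, uncomplete = 2,
    complete = 3, present = 3)[lvl]
}

rule_symbols <- function(rules, pathway) {
  sort(unique(unlist(lapply(rules[[pathway]]$rules, function(r)
    all.vars(parse(text = r)[[1]])))))
}
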