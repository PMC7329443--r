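#' Two-sided Fisher's exact test for a 2x2 contingency table
#'
#' The table is `rbind(c(a, b), c(c, d))` with rows = samples: `a`/`c` are
#' reads mapped to the gene in samples 1/2 and `b`/`d` the remaining reads.
#' The two-sided p-value follows the probability-mass rule: sum, over all
#' tables with the observed margins, of those hypergeometric probabilities
#' not exceeding the observed one (with a 1e-7 relative tolerance on the
#' comparison, the usual guard against floating-point ties).
#'
#' @param a,b,c,d Non-negative integer counts; `a + b > 0` and `c + d > 0`.
#' @return p-value in [0, 1]. Degenerate gene margins (`a + c == 0` or
#'   `b + d == 0`) return 1.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b > 0, c + d > 0)
  m <- a + c          # reads on the gene (both samples)
  n <- b + d          # reads elsewhere
  k <- a + b          # sample-1 total
  if (m == 0 || n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  p <- sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-7)])
  min(1, p)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Successes, `0 <= x <= n`.
#' @param n Trials, > 0.
#' @param conf Confidence level (default 0.95).
#' @return Numeric `c(low, high)` with `0 <= low <= x/n <= high <= 1`.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- qnorm((1 + conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # clamp against floating-point loss so low <= p <= high always holds
  c(low = min(max(0, centre - half), p), high = max(min(1, centre + half), p))
}

#' Newcombe's score interval for a difference of proportions
#'
#' Composes the two Wilson intervals (l1, u1) and (l2, u2): with
#' \eqn{\Delta = \hat p_1 - \hat p_2},
#' \deqn{low = \Delta - \sqrt{(\hat p_1 - l_1)^2 + (u_2 - \hat p_2)^2},
#'       \quad
#'       high = \Delta + \sqrt{(u_1 - \hat p_1)^2 + (\hat p_2 - l_2)^2}.}
#'
#' @param x1,n1 Successes/trials in sample 1.
#' @param x2,n2 Successes/trials in sample 2.
#' @param conf Confidence level (default 0.95).
#' @return Numeric `c(low, high)`, bounded to [-1, 1] and containing
#'   `x1/n1 - x2/n2`.
#' @export
newcombe_diff_interval <- function(x1, n1, x2, n2, conf = 0.95) {
  w1 <- wilson_interval(x1, n1, conf)
  w2 <- wilson_interval(x2, n2, conf)
  p1 <- x1 / n1
  p2 <- x2 / n2
  delta <- p1 - p2
  c(low = max(-1, delta - sqrt((p1 - w1[["low"]])^2 +
                                 (w2[["high"]] - p2)^2)),
    high = min(1, delta + sqrt((w1[["high"]] - p1)^2 +
                                 (p2 - w2[["low"]])^2)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper over `stats::p.adjust(p, "BH")`: step-up
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, mapped back to input
#' order and capped at 1.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Differential gene abundance between two metagenomes
#'
#' For each gene symbol, aggregates raw mapped-read counts over the genes
#' carrying it in each sample and tests the 2x2 table (symbol reads vs all
#' other reads in that sample) with a two-sided Fisher's exact test; the
#' difference of the two symbol read proportions gets a Newcombe-Wilson
#' confidence interval, and p-values are BH-adjusted across all symbols
#' tested in the call. Tests use raw integer counts; the per-million
#' normalized abundances are reported alongside but never tested.
#'
#' @param genes_a,genes_b Gene tables for the two samples (columns
#'   `symbol`, `length`, `reads`).
#' @param symbols Symbols to test; default the union of symbols observed in
#'   either sample. Symbols present in neither are skipped with a message.
#' @param alpha FDR significance threshold (default 0.05).
#' @param conf Confidence level for the interval (default 0.95).
#' @param aggregate If `FALSE`, test each `gene_id` individually instead of
#'   aggregating per symbol.
#' @return `data.frame` (class `vent_diff`) with one row per tested symbol:
#'   counts, proportions, `delta`, `ci_low`, `ci_high`, `p`, `q`,
#'   `significant` (q < alpha), `direction` ("A", "B" or "none") and the
#'   per-million abundances `abund_a`, `abund_b`.
#' @export
compare_metagenomes <- function(genes_a, genes_b, symbols = NULL,
                                alpha = 0.05, conf = 0.95,
                                aggregate = TRUE) {
  stopifnot(sum(genes_a$reads) > 0, sum(genes_b$reads) > 0)
  key <- if (aggregate) "symbol" else "gene_id"
  symbols <- symbols %||% sort(unique(c(genes_a[[key]][genes_a$reads > 0],
                                        genes_b[[key]][genes_b$reads > 0])))
  tot_a <- sum(genes_a$reads)
  tot_b <- sum(genes_b$reads)
  na <- normalize_abundance(genes_a)
  nb <- normalize_abundance(genes_b)
  absent <- symbols[!(symbols %in% genes_a[[key]]) &
                      !(symbols %in% genes_b[[key]])]
  if (length(absent)) {
    message("compare_metagenomes: skipping symbols absent from both samples: ",
            paste(absent, collapse = ", "))
    symbols <- setdiff(symbols, absent)
  }
  rows <- lapply(symbols, function(s) {
    xa <- sum(genes_a$reads[genes_a[[key]] == s])
    xb <- sum(genes_b$reads[genes_b[[key]] == s])
    ci <- newcombe_diff_interval(xa, tot_a, xb, tot_b, conf)
    data.frame(
      symbol = s, reads_a = xa, reads_b = xb,
      prop_a = xa / tot_a, prop_b = xb / tot_b,
      delta = xa / tot_a - xb / tot_b,
      ci_low = ci[["low"]], ci_high = ci[["high"]],
      p = fisher_exact_two_sided(xa, tot_a - xa, xb, tot_b - xb),
      abund_a = sum(na$abundance[na[[key]] == s]),
      abund_b = sum(nb$abundance[nb[[key]] == s]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$delta > 0, "A", "B"))
  out <- out[, c("symbol", "reads_a", "reads_b", "prop_a", "prop_b",
                 "delta", "ci_low", "ci_high", "p", "q", "significant",
                 "direction", "abund_a", "abund_b")]
  class(out) <- c("vent_diff", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "conf") <- conf
  out
}

#' @export
print.vent_diff <- function(x, ...) {
  cat(sprintf("Differential gene abundance: %d symbols tested, %d at q < %g\n",
              nrow(x), sum(x$significant), attr(x, "alpha")))
  print.data.frame(head(x[order(x$q), ], 10), digits = 3, row.names = FALSE)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
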