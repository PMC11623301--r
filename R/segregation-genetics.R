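# Segregation expectations and exact tests for haploid crosses: the
# genetics behind element-linked resistance phenotypes.

#' Expected resistant fraction under unlinked dominant loci
#'
#' Probability that a haploid progeny inherits at least one of `n_loci`
#' unlinked resistance loci from a cross between a parent carrying all of
#' them and a parent carrying none, each segregating 1:1:
#' `1 - (1 - p)^n_loci`.  One locus gives the textbook 50%; two unlinked
#' loci give 75%.
#'
#' @param n_loci number of unlinked resistance loci (>= 0).
#' @param p per-locus inheritance probability.
#' @return expected fraction in `[0, 1]`.
#' @export
#' @examples
#' expected_resistant_fraction(1)  # 0.5
#' expected_resistant_fraction(2)  # 0.75
expected_resistant_fraction <- function(n_loci, p = 0.5) {
  if (n_loci < 0) stop("n_loci must be non-negative")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  1 - (1 - p)^n_loci
}

#' Two-sided exact binomial test (point-probability method)
#'
#' The two-sided p-value is the sum of `P(X = i)` over every outcome `i`
#' whose point probability does not exceed that of the observed `k`
#' (with the conventional `1 + 1e-7` relative fuzz against floating-point
#' ties), under `X ~ Binomial(n, p0)`.
#'
#' @param k observed successes, `0 <= k <= n`.
#' @param n trials (>= 1).
#' @param p0 null success probability.
#' @return a `seg_test` list with `k`, `n`, `p0` and `p_value`.
#' @export
#' @examples
#' exact_binomial_test(11, 22, 0.5)$p_value  # 1: the modal outcome
#' exact_binomial_test(22, 22, 0.5)$p_value  # 2 * 0.5^22
exact_binomial_test <- function(k, n, p0 = 0.5) {
  if (n < 1) stop("n must be at least 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]")
  probs <- stats::dbinom(0:n, n, p0)
  pk <- probs[k + 1L]
  p <- min(1, sum(probs[probs <= pk * (1 + 1e-7)]))
  structure(list(k = as.integer(k), n = as.integer(n), p0 = p0, p_value = p),
            class = "seg_test")
}

#' @export
print.seg_test <- function(x, ...) {
  cat(sprintf("<seg_test> %d/%d successes vs p0 = %g: exact two-sided p = %.4g\n",
              x$k, x$n, x$p0, x$p_value))
  invisible(x)
}

#' Marker-phenotype cosegregation test
#'
#' Builds the 2x2 marker-by-phenotype contingency table over progeny and
#' computes the two-sided Fisher exact p-value by hypergeometric
#' enumeration (point-probability method).  Segregation is reported as
#' "perfect" when both off-diagonal cells are zero.
#'
#' @param marker logical/0-1 vector: marker (element) presence per progeny.
#' @param phenotype logical/0-1 vector of equal length: phenotype per
#'   progeny.
#' @return list with `table` (2x2 matrix), `p_value` and `perfect`.
#' @export
cosegregation_test <- function(marker, phenotype) {
  marker <- as.logical(marker)
  phenotype <- as.logical(phenotype)
  if (length(marker) != length(phenotype)) {
    stop("marker and phenotype vectors differ in length")
  }
  if (length(marker) < 1L) stop("need at least one progeny")
  if (anyNA(marker) || anyNA(phenotype)) stop("missing values not allowed")
  tab <- matrix(c(
    sum(marker & phenotype), sum(marker & !phenotype),
    sum(!marker & phenotype), sum(!marker & !phenotype)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(marker = c("marker+", "marker-"),
                  phenotype = c("pheno+", "pheno-")))
  # hypergeometric enumeration at fixed margins
  m <- sum(tab[1, ])          # marker+ progeny
  nn <- sum(tab[2, ])         # marker- progeny
  kk <- sum(tab[, 1])         # pheno+ progeny
  x <- tab[1, 1]
  support <- max(0L, kk - nn):min(kk, m)
  probs <- stats::dhyper(support, m, nn, kk)
  px <- probs[match(x, support)]
  p <- min(1, sum(probs[probs <= px * (1 + 1e-7)]))
  list(table = tab, p_value = p,
       perfect = tab[1, 2] == 0L && tab[2, 1] == 0L)
}
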