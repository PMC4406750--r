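#' Welch's two-sample t-test
#'
#' Unequal-variance two-sample t-test with the Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. This is the per-feature test used for both
#' methylation loci (on beta values) and expression probes (on log2
#' intensities), where group variances cannot be assumed equal.
#'
#' Degenerate inputs are resolved deterministically rather than propagating
#' `NaN`: if both groups have zero variance the statistic is 0 and p = 1 when
#' the means agree, and +/-Inf with p = 0 when they differ.
#'
#' @param a,b Numeric vectors with at least two observations each.
#' @return A list with components `mean_a`, `mean_b`, `delta` (`mean_a -
#'   mean_b`), `t_stat`, `df` (fractional Welch-Satterthwaite value) and
#'   `p_value` (two-sided).
#' @examples
#' welchTTest(c(0.1, 0.2, 0.3), c(0.5, 0.6, 0.7))
#' @seealso [rowWelchTests()] for the vectorised matrix form.
#' @export
welchTTest <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("welchTTest: each group needs at least 2 observations")
  if (anyNA(a) || anyNA(b))
    stop("welchTTest: missing values are not allowed")
  res <- rowWelchTests(matrix(a, nrow = 1L), matrix(b, nrow = 1L))
  list(mean_a = res$mean_a, mean_b = res$mean_b, delta = res$delta,
       t_stat = res$t_stat, df = res$df, p_value = res$p_value)
}

#' Row-wise Welch t-tests
#'
#' Vectorised Welch t-tests across the rows of two matrices holding the two
#' groups' samples in columns. Used to test every methylation locus or
#' expression probe of a comparison in one call.
#'
#' @param ma,mb Numeric matrices with one row per feature; `ma` holds the
#'   first group's samples in columns, `mb` the second group's. Row counts
#'   must agree.
#' @return A data.frame with one row per feature: `mean_a`, `mean_b`,
#'   `delta`, `t_stat`, `df`, `p_value`.
#' @export
rowWelchTests <- function(ma, mb) {
  ma <- as.matrix(ma); mb <- as.matrix(mb)
  if (nrow(ma) != nrow(mb))
    stop("rowWelchTests: row counts differ")
  na <- ncol(ma); nb <- ncol(mb)
  if (na < 2L || nb < 2L)
    stop("rowWelchTests: each group needs at least 2 samples")
  mean_a <- rowMeans(ma)
  mean_b <- rowMeans(mb)
  va <- rowSums((ma - mean_a)^2) / (na - 1L)
  vb <- rowSums((mb - mean_b)^2) / (nb - 1L)
  sea <- va / na
  seb <- vb / nb
  se2 <- sea + seb
  delta <- mean_a - mean_b
  t_stat <- ifelse(se2 > 0, delta / sqrt(se2),
                   ifelse(delta == 0, 0, sign(delta) * Inf))
  # Welch-Satterthwaite; df is irrelevant where se2 == 0 (t is 0 or Inf)
  df <- ifelse(se2 > 0,
               se2^2 / (sea^2 / (na - 1L) + seb^2 / (nb - 1L)),
               1)
  p_value <- ifelse(is.infinite(t_stat), 0,
                    2 * stats::pt(-abs(t_stat), df))
  data.frame(mean_a = mean_a, mean_b = mean_b, delta = delta,
             t_stat = t_stat, df = df, p_value = pmin(p_value, 1))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values. The
#' method is configurable (any method accepted by [stats::p.adjust()]) but
#' defaults to Benjamini-Hochberg, the standard array q-value.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method Adjustment method, default `"BH"`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bhAdjust <- function(p, method = "BH") {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("bhAdjust: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

.checkHypergeomCounts <- function(N, K, m, k, requireK = FALSE) {
  for (v in list(N, K, m, k))
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stop("hypergeometric counts must be single nonnegative integers")
  if (K > N || m > N) stop("K and m must not exceed the background size N")
  if (k > K || k > m) stop("overlap k must not exceed K or m")
  if (requireK && (K == 0 || m == 0 || N == 0))
    stop("fold enrichment requires N, K and m all positive")
  invisible(TRUE)
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric with background size `N`, `K` marked
#' genes (the pathway) and `m` draws (the query set). This is the
#' over-representation p-value of observing at least `k` query genes inside
#' the pathway.
#'
#' @param N Background (universe) size.
#' @param K Pathway genes in the background.
#' @param m Query-set genes in the background.
#' @param k Observed overlap.
#' @return The upper-tail probability, in \[0, 1\].
#' @examples
#' hypergeomUpperTail(N = 10, K = 5, m = 5, k = 5)  # 1/252
#' @export
hypergeomUpperTail <- function(N, K, m, k) {
  .checkHypergeomCounts(N, K, m, k)
  stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
}

#' Fold enrichment
#'
#' The query set's in-pathway fraction relative to the background's:
#' `(k/m) / (K/N)`. A value of 1 means no enrichment; `k = 0` gives 0.
#'
#' @inheritParams hypergeomUpperTail
#' @return The fold enrichment as a single number.
#' @examples
#' foldEnrichment(N = 17450, K = 129, m = 366, k = 13)  # ~4.80
#' @export
foldEnrichment <- function(N, K, m, k) {
  .checkHypergeomCounts(N, K, m, k, requireK = TRUE)
  (k / m) / (K / N)
}
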