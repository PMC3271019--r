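.test_result <- function(test_name, statistic, p_value, n_a, n_b,
                         details = list()) {
  stopifnot(is.finite(statistic), p_value >= 0, p_value <= 1)
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, n_a = n_a, n_b = n_b, details = details),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.3g (n_a = %d, n_b = %d)\n",
              x$test_name, x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic `D = max_x |ECDF_a(x) - ECDF_b(x)|`, the maximum distance
#' between the two empirical cumulative curves, with the asymptotic
#' two-sided p-value at effective sample size `n_a n_b / (n_a + n_b)` —
#' appropriate for the sample sizes this screen works at. An exact
#' small-sample mode is available.
#'
#' @param a,b Numeric samples, both nonempty.
#' @param exact Use the exact small-sample p-value instead of the
#'   asymptotic one (default `FALSE`).
#' @return A `"test_result"` with the D statistic.
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  if (!length(a) || !length(b))
    stop("KS test requires two nonempty samples", call. = FALSE)
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  .test_result("ks_two_sample", unname(res$statistic),
               min(1, unname(res$p.value)), length(a), length(b),
               details = list(effective_n = length(a) * length(b) /
                                (length(a) + length(b))))
}

#' Upper tail of the hypergeometric distribution
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: `k` marked items in a
#' draw of `n` from a pool of `N` containing `K` marked items. Evaluated on
#' the numerically stable `lower.tail = FALSE` path.
#'
#' @param k Observed count of marked items in the draw.
#' @param K Number of marked items in the pool.
#' @param n Draw size.
#' @param N Pool size.
#' @return The tail probability.
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (!(k >= 0 && k <= min(n, K) && min(n, K) <= N && K <= N && n <= N))
    stop("inconsistent hypergeometric parameters: need 0 <= k <= min(n, K) <= N",
         call. = FALSE)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Enrichment test for a one-sided sign pattern across families
#'
#' Tests whether viral proteins are shorter than their metazoan
#' counterparts in more families than chance predicts: with `n_shorter` of
#' `n_families` families showing the pattern, the default is the one-sided
#' binomial sign test `P[X >= n_shorter]` for `X ~ Binomial(n_families,
#' p0)` with `p0 = 0.5`. A hypergeometric mode (drawing family outcomes
#' from a finite pool of `pool_size` families of which `pool_marked` show
#' the pattern) is available; both parametrizations are reported rather
#' than silently chosen.
#'
#' @param n_families Number of families scored.
#' @param n_shorter Number showing the pattern.
#' @param p0 Null success probability for the binomial mode (default 0.5).
#' @param method `"binomial"` (default) or `"hypergeometric"`.
#' @param pool_size,pool_marked Pool parameters for the hypergeometric mode.
#' @return A `"test_result"`; the statistic is the observed fraction.
#' @export
sign_enrichment <- function(n_families, n_shorter, p0 = 0.5,
                            method = c("binomial", "hypergeometric"),
                            pool_size = NULL, pool_marked = NULL) {
  method <- match.arg(method)
  stopifnot(n_shorter >= 0, n_shorter <= n_families)
  if (method == "binomial") {
    p <- stats::pbinom(n_shorter - 1, size = n_families, prob = p0,
                       lower.tail = FALSE)
    details <- list(method = "binomial", p0 = p0)
  } else {
    if (is.null(pool_size) || is.null(pool_marked))
      stop("hypergeometric mode needs pool_size and pool_marked", call. = FALSE)
    p <- hypergeometric_tail(n_shorter, pool_marked, n_families, pool_size)
    details <- list(method = "hypergeometric", pool_size = pool_size,
                    pool_marked = pool_marked)
  }
  .test_result("sign_enrichment", n_shorter / n_families, p,
               n_families, n_families, details)
}

#' Paired t test
#'
#' Classical paired t on per-family pairs (e.g. mean viral vs mean metazoan
#' domain counts, aligned by family): t is the mean difference over its
#' standard error, two-sided p from the t distribution with `n - 1` degrees
#' of freedom.
#'
#' @param a,b Numeric vectors of equal length (>= 2), pairs aligned.
#' @return A `"test_result"` with the t statistic and `df` in `details`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("paired t requires two equal-length samples of size >= 2",
         call. = FALSE)
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0))
      return(.test_result("paired_t", 0, 1, length(a), length(b),
                          details = list(df = length(a) - 1L)))
    stop("degenerate input: differences have zero variance", call. = FALSE)
  }
  n <- length(d)
  t <- mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE)
  .test_result("paired_t", t, p, n, n, details = list(df = n - 1L))
}

#' Cumulative fraction table on an integer grid
#'
#' The empirical cumulative fraction of a sample evaluated at every integer
#' from 0 to `grid_max` — the tabular form of the cumulative curves used
#' for linker-length comparisons.
#'
#' @param values Nonempty numeric sample.
#' @param grid_max Upper end of the integer grid.
#' @return data.frame with columns `x` (0..`grid_max`) and `cum_fraction`,
#'   monotone non-decreasing and bounded by 1.
#' @export
ecdf_table <- function(values, grid_max) {
  if (!length(values)) stop("ecdf_table requires a nonempty sample", call. = FALSE)
  x <- 0:grid_max
  data.frame(x = x, cum_fraction = stats::ecdf(values)(x))
}
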