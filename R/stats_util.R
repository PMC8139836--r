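#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution when the pooled sample has at most `exact_max`
#' observations and no ties; otherwise the normal approximation with midrank
#' tie correction and no continuity correction (so that identical samples
#' give p = 1).
#'
#' @param x,y numeric samples (each nonempty).
#' @param exact_max pooled-size limit for the exact method (default 12).
#' @return a list of class `test_result` with `statistic`, `p_value`, `n1`,
#'   `n2`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 12) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  pooled <- c(x, y)
  ties <- any(duplicated(pooled))
  exact <- (length(pooled) <= exact_max) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n1 = length(x), n2 = length(y),
                 method = if (exact) "rank-sum (exact)" else
                   "rank-sum (normal approximation)"),
            class = "test_result")
}

#' Two-sided Wilcoxon signed-rank test of zero median
#'
#' Zero differences are dropped first; exact when at most `exact_max`
#' nonzero differences without tied magnitudes, otherwise the normal
#' approximation with tie correction and no continuity correction.
#'
#' @param d paired differences (at least one nonzero).
#' @param exact_max sample-size limit for the exact method (default 15).
#' @return a `test_result` with `statistic`, `p_value`, `n` (nonzero
#'   differences), `method`.
#' @export
signed_rank_test <- function(d, exact_max = 15) {
  d <- d[d != 0]
  if (length(d) == 0) stop("all differences are zero")
  ties <- any(duplicated(abs(d)))
  exact <- (length(d) <= exact_max) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = FALSE))
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n = length(d),
                 method = if (exact) "signed-rank (exact)" else
                   "signed-rank (normal approximation)"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic=%g, p=%.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate; a thin
#' validating wrapper around [stats::p.adjust()].
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Percentile bootstrap confidence interval
#'
#' Draws `B` resamples with replacement, evaluates the statistic on each,
#' and returns the percentile interval. Deterministic given `seed`.
#'
#' @param x numeric sample (nonempty).
#' @param statistic function of a numeric vector (default [mean()]).
#' @param B number of resamples (>= 100, default 1000).
#' @param seed optional RNG seed; `NULL` uses the current RNG state.
#' @param level confidence level (default 0.95).
#' @return numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(x, statistic = mean, B = 1000, seed = NULL,
                         level = 0.95) {
  if (length(x) == 0) stop("empty sample")
  if (B < 100) stop("B must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  stats_b <- vapply(seq_len(B), function(b) {
    statistic(x[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - level) / 2
  unname(stats::quantile(stats_b, c(alpha, 1 - alpha), type = 7))
}
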