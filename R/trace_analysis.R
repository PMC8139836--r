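#' Ratiometric calcium activity from a two-channel trace
#'
#' Computes `R(t) = green/red`, takes the baseline `R0` as the 1st
#' percentile of `R(t)` (linear-interpolation quantile), and returns the
#' activity `dR/R0 = (R - R0)/R0`. Activity is bounded below by -1 and, by
#' construction of the percentile baseline, about 1% of frames fall below 0.
#'
#' @param raw a `data.frame` with columns `time`, `green`, `red` (both
#'   intensities > 0) and optionally `motor_state`.
#' @param baseline_quantile baseline percentile (default 0.01).
#' @return a `data.frame` of class `activity_series` with columns `time`,
#'   `activity` (and `motor_state` if present), and attribute `R0`.
#' @export
ratiometric_activity <- function(raw, baseline_quantile = 0.01) {
  stopifnot(all(c("time", "green", "red") %in% names(raw)))
  if (any(raw$red <= 0)) stop("red channel must be positive on every frame")
  if (any(raw$green <= 0)) stop("green channel must be positive on every frame")
  R <- raw$green / raw$red
  R0 <- as.numeric(stats::quantile(R, baseline_quantile, type = 7))
  out <- data.frame(time = raw$time, activity = (R - R0) / R0)
  if (!is.null(raw$motor_state)) out$motor_state <- raw$motor_state
  attr(out, "R0") <- R0
  class(out) <- c("activity_series", "data.frame")
  out
}

#' Otsu threshold of a 1-D signal
#'
#' Builds a 256-bin equal-width histogram over the sample range and returns
#' the threshold (a bin edge) maximizing the between-class variance; ties
#' are broken toward the lower threshold. Samples at or above the threshold
#' are classified ON.
#'
#' @param x numeric signal with at least 2 distinct values (an
#'   `activity_series` is accepted and its `activity` column used).
#' @param n_bins histogram resolution (default 256).
#' @return a list with `threshold`, `on` (logical per sample), and
#'   `between_var` (the achieved between-class variance).
#' @export
otsu_binarize <- function(x, n_bins = 256) {
  if (inherits(x, "activity_series")) x <- x$activity
  x <- as.numeric(x)
  if (length(unique(x)) < 2) stop("degenerate histogram: constant series")
  lo <- min(x)
  hi <- max(x)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE),
                               1L), n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  n <- length(x)
  ## cumulative statistics; candidate cut after bin k puts bins 1..k below
  w0 <- cumsum(counts) / n
  mu_cum <- cumsum(counts * mids) / n
  mu_tot <- mu_cum[n_bins]
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu_tot * w0[valid] - mu_cum[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(bcv)  # which.max takes the first (lowest) maximizer
  thr <- edges[k + 1]
  list(threshold = thr, on = x >= thr, between_var = bcv[k])
}

## squared-distance-weighted seeding for EM initialization (k-means++)
kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  if (k > 1) {
    for (j in 2:k) {
      d2 <- vapply(x, function(xi) min((xi - centers[seq_len(j - 1)])^2),
                   numeric(1))
      if (sum(d2) == 0) {
        centers[j] <- x[sample.int(length(x), 1)]
      } else {
        centers[j] <- x[sample.int(length(x), 1, prob = d2)]
      }
    }
  }
  centers
}

## EM for a univariate Gaussian mixture; returns NULL on failure
gmm_em <- function(x, k, tol = 1e-6, max_iter = 500, var_floor) {
  n <- length(x)
  mu <- kmeanspp_centers(x, k)
  sigma2 <- rep(stats::var(x), k)
  w <- rep(1 / k, k)
  loglik <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) {
      w[j] * stats::dnorm(x, mu[j], sqrt(sigma2[j]))
    }, numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- rowSums(dens)
    if (any(rowsum_d <= 0) || any(!is.finite(rowsum_d))) return(NULL)
    ll <- sum(log(rowsum_d))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(loglik) && abs(ll - loglik) < tol) {
      loglik <- ll
      break
    }
    loglik <- ll
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma2 <- vapply(seq_len(k), function(j) {
      sum(resp[, j] * (x - mu[j])^2) / nk[j]
    }, numeric(1))
    sigma2 <- pmax(sigma2, var_floor)
  }
  list(weights = w, means = mu, variances = sigma2, loglik = loglik,
       ll_trace = ll_trace, converged = it < max_iter)
}

#' Fit Gaussian mixtures to an activity distribution and select k by BIC
#'
#' Fits univariate Gaussian mixtures with `k` in `k_range` by EM, each
#' initialized from k-means++ cluster centers with uniform mixing
#' proportions, and returns the model minimizing
#' `BIC = -2 logL + (3k - 1) log n`. Each `k` gets `n_restarts` seeded
#' restarts and keeps the best log-likelihood; a `k` whose restarts all fail
#' is skipped with a warning.
#'
#' @param x numeric sample (an `activity_series` is accepted); needs at
#'   least `10 * k` samples for each candidate `k`.
#' @param k_range candidate component counts (default `1:6`).
#' @param n_restarts EM restarts per `k` (default 5).
#' @param seed RNG seed for reproducible initialization (default 1).
#' @param tol EM log-likelihood tolerance (default 1e-6).
#' @return an object of class `mixture_fit`: `k`, `weights`, `means`,
#'   `variances`, `bic` (selected), `bic_by_k`, `loglik`, `ll_trace`,
#'   `converged`, `seed`, `n`.
#' @export
fit_mixture <- function(x, k_range = 1:6, n_restarts = 5, seed = 1,
                        tol = 1e-6) {
  if (inherits(x, "activity_series")) x <- x$activity
  x <- as.numeric(x)
  k_range <- k_range[10 * k_range <= length(x)]
  if (length(k_range) == 0) stop("too few samples for any candidate k")
  var_floor <- 1e-6 * stats::var(x)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  bic_by_k <- stats::setNames(rep(NA_real_, length(k_range)),
                              paste0("k", k_range))
  n <- length(x)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit_k <- NULL
    for (r in seq_len(n_restarts)) {
      f <- gmm_em(x, k, tol = tol, var_floor = var_floor)
      if (!is.null(f) && (is.null(fit_k) || f$loglik > fit_k$loglik)) {
        fit_k <- f
      }
    }
    if (is.null(fit_k)) {
      warning("EM failed for all restarts at k = ", k, "; skipped")
      next
    }
    bic <- -2 * fit_k$loglik + (3 * k - 1) * log(n)
    bic_by_k[i] <- bic
    if (is.null(best) || bic < best$bic) {
      ord <- order(fit_k$means)
      best <- list(k = k, weights = fit_k$weights[ord],
                   means = fit_k$means[ord],
                   variances = fit_k$variances[ord], bic = bic,
                   loglik = fit_k$loglik, ll_trace = fit_k$ll_trace,
                   converged = fit_k$converged)
    }
  }
  if (is.null(best)) stop("mixture fitting failed for every candidate k")
  best$bic_by_k <- bic_by_k
  best$seed <- seed
  best$n <- n
  class(best) <- "mixture_fit"
  best
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k=%d (BIC=%.1f, n=%d)\n", x$k, x$bic, x$n))
  print(round(data.frame(weight = x$weights, mean = x$means,
                         variance = x$variances), 4))
  invisible(x)
}

#' Activation threshold from a mixture fit
#'
#' Solves for the point between the two lowest component means where the two
#' weight-scaled Gaussian densities are equal (the decision boundary), via
#' the closed-form quadratic in the log-densities. If no root lies strictly
#' between the two means, the midpoint is returned with a warning.
#'
#' @param fit a [fit_mixture()] result with `k >= 2`.
#' @return the activation threshold (scalar).
#' @export
activation_threshold <- function(fit) {
  if (fit$k < 2) stop("activation threshold requires a fit with k >= 2")
  ord <- order(fit$means)
  i <- ord[1]
  j <- ord[2]
  m1 <- fit$means[i]; m2 <- fit$means[j]
  v1 <- fit$variances[i]; v2 <- fit$variances[j]
  w1 <- fit$weights[i]; w2 <- fit$weights[j]
  ## log w1 - log(sqrt v1) - (x-m1)^2/(2 v1) = log w2 - ... : a x^2 + b x + c
  a <- 1 / (2 * v2) - 1 / (2 * v1)
  b <- m1 / v1 - m2 / v2
  cc <- m2^2 / (2 * v2) - m1^2 / (2 * v1) +
    log(w1 / sqrt(v1)) - log(w2 / sqrt(v2))
  if (abs(a) < 1e-14) {
    root <- if (abs(b) > 0) -cc / b else NA_real_
    roots <- root
  } else {
    disc <- b^2 - 4 * a * cc
    roots <- if (disc < 0) numeric(0) else {
      (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    }
  }
  inside <- roots[is.finite(roots) & roots > m1 & roots < m2]
  if (length(inside) == 0) {
    warning("no density intersection strictly between the two lowest ",
            "means; falling back to their midpoint")
    return((m1 + m2) / 2)
  }
  inside[1]
}

#' Supra-threshold activation epochs
#'
#' Maximal intervals where the activity exceeds the threshold, with their
#' durations.
#'
#' @param series an `activity_series` (or a `data.frame` with `time` and
#'   `activity`).
#' @param threshold activation threshold.
#' @return a `data.frame` with `i_start`, `i_end`, `t_start`, `t_end`,
#'   `duration` (possibly zero rows).
#' @export
activation_epochs <- function(series, threshold) {
  act <- series$activity
  tt <- series$time
  on <- act > threshold
  if (!any(on)) {
    return(data.frame(i_start = integer(0), i_end = integer(0),
                      t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0)))
  }
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  keep <- r$values
  starts <- starts[keep]
  ends <- ends[keep]
  dt <- if (length(tt) >= 2) tt[2] - tt[1] else 1
  data.frame(i_start = starts, i_end = ends,
             t_start = tt[starts], t_end = tt[ends],
             duration = (ends - starts + 1L) * dt)
}
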