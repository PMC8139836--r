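#' Event-triggered activity matrix
#'
#' Extracts one row of activity per event, aligned on the event frame, over
#' `pre_window` before and `post_window` after the event. Frames falling
#' outside the recording are `NA` and excluded from the per-lag mean (never
#' zero-filled).
#'
#' @param activity an `activity_series` (columns `time`, `activity`).
#' @param event_times event times (same clock as `activity$time`).
#' @param pre_window,post_window window extents in time units (> 0).
#' @return a list of class `eta_matrix`: `lags` (seconds relative to the
#'   event), `matrix` (events x lags), `mean` (per-lag mean over available
#'   entries), `n_events`.
#' @export
event_triggered_matrix <- function(activity, event_times, pre_window,
                                   post_window) {
  stopifnot(pre_window > 0, post_window > 0)
  if (length(event_times) == 0) stop("no events")
  tt <- activity$time
  dt <- tt[2] - tt[1]
  pre_n <- round(pre_window / dt)
  post_n <- round(post_window / dt)
  lag_idx <- seq(-pre_n, post_n)
  m <- matrix(NA_real_, nrow = length(event_times), ncol = length(lag_idx))
  for (e in seq_along(event_times)) {
    i0 <- which.min(abs(tt - event_times[e]))
    idx <- i0 + lag_idx
    ok <- idx >= 1 & idx <= length(tt)
    m[e, ok] <- activity$activity[idx[ok]]
  }
  if (all(is.na(m))) stop("no events with any covered frames")
  structure(list(lags = lag_idx * dt, matrix = m,
                 mean = colMeans(m, na.rm = TRUE),
                 n_events = length(event_times)),
            class = "eta_matrix")
}

#' Pre/post activity change around events
#'
#' Per event, the difference between the mean activity in the post window
#' and the mean in the pre window (the event frame itself excluded), with a
#' bootstrap confidence interval on the mean change and a two-sided Wilcoxon
#' signed-rank test against a zero median.
#'
#' @inheritParams event_triggered_matrix
#' @param B bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @return a list: `delta` (per event, `NA` where a window had no covered
#'   frames), `mean`, `ci`, `test` (a `test_result`), `n`.
#' @export
pre_post_change <- function(activity, event_times, pre_window = 5,
                            post_window = 5, B = 1000, conf = 0.95) {
  stopifnot(pre_window > 0, post_window > 0)
  if (length(event_times) == 0) stop("no events")
  tt <- activity$time
  act <- activity$activity
  dt <- tt[2] - tt[1]
  pre_n <- round(pre_window / dt)
  post_n <- round(post_window / dt)
  delta <- vapply(event_times, function(te) {
    i0 <- which.min(abs(tt - te))
    pre_idx <- seq(i0 - pre_n, i0 - 1)
    post_idx <- seq(i0 + 1, i0 + post_n)
    pre_idx <- pre_idx[pre_idx >= 1 & pre_idx <= length(tt)]
    post_idx <- post_idx[post_idx >= 1 & post_idx <= length(tt)]
    if (length(pre_idx) == 0 || length(post_idx) == 0) return(NA_real_)
    mean(act[post_idx]) - mean(act[pre_idx])
  }, numeric(1))
  if (any(is.na(delta))) {
    warning("skipping ", sum(is.na(delta)), " event(s) with no covered frames")
  }
  d <- delta[!is.na(delta)]
  if (length(d) == 0) stop("no events with covered frames")
  test <- if (any(d != 0)) signed_rank_test(d) else NULL
  ci <- if (length(d) > 1) bootstrap_ci(d, mean, B = B, level = conf) else
    c(d, d)
  list(delta = delta, mean = mean(d), ci = ci, test = test, n = length(d))
}

## per-epoch Pearson cross-correlation at a set of lags, then averaged.
## positive lag means `b` follows `a` by that many frames.
epoch_xcorr <- function(a, b, epochs, max_lag_n, min_pts = 3) {
  lags <- seq(-max_lag_n, max_lag_n)
  acc <- matrix(NA_real_, nrow = length(epochs), ncol = length(lags))
  for (e in seq_along(epochs)) {
    idx <- epochs[[e]]
    xa <- a[idx] - mean(a[idx])
    xb <- b[idx] - mean(b[idx])
    n <- length(idx)
    for (li in seq_along(lags)) {
      L <- lags[li]
      if (n - abs(L) < min_pts) next
      if (L >= 0) {
        u <- xa[seq_len(n - L)]
        v <- xb[seq(L + 1, n)]
      } else {
        u <- xa[seq(-L + 1, n)]
        v <- xb[seq_len(n + L)]
      }
      su <- stats::sd(u)
      sv <- stats::sd(v)
      if (su == 0 || sv == 0) next
      acc[e, li] <- stats::cor(u, v)
    }
  }
  list(lags = lags, mean = colMeans(acc, na.rm = TRUE), per_epoch = acc)
}

#' Cross-correlogram between stimulus and activity, conditioned on motor
#' state
#'
#' For each motor state, computes the Pearson cross-correlation within every
#' constant-state epoch of at least `min_epoch` duration (mean-subtracting
#' within the epoch) and averages across epochs at each lag. Positive lags
#' mean the activity follows the stimulus.
#'
#' @param stimulus numeric stimulus series (same sampling grid as the
#'   activity).
#' @param activity an `activity_series` or numeric vector.
#' @param states per-frame motor-state labels (1 forward / 0 reversal).
#' @param frame_dt frame interval.
#' @param max_lag maximum lag in time units (default 10).
#' @param min_epoch minimum epoch duration in time units (default 3).
#' @return a list of class `xcorr_result` per state (`forward`,
#'   `reversal`), each with `lags` (time units), `r` (mean correlation per
#'   lag), `n_epochs`, `peak_r`, `peak_lag`; states without a long-enough
#'   epoch are flagged `empty = TRUE`.
#' @export
state_conditioned_xcorr <- function(stimulus, activity, states, frame_dt,
                                    max_lag = 10, min_epoch = 3) {
  act <- if (inherits(activity, "data.frame")) activity$activity else activity
  if (length(stimulus) != length(act) || length(act) != length(states)) {
    stop("stimulus, activity and states must share one sampling grid")
  }
  max_lag_n <- round(max_lag / frame_dt)
  min_n <- max(2L, round(min_epoch / frame_dt))
  r <- rle(as.integer(states))
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- list()
  for (st in c(1L, 0L)) {
    name <- if (st == 1L) "forward" else "reversal"
    sel <- which(r$values == st & r$lengths >= min_n)
    if (length(sel) == 0) {
      out[[name]] <- list(empty = TRUE, n_epochs = 0L)
      next
    }
    epochs <- lapply(sel, function(i) seq(starts[i], ends[i]))
    xc <- epoch_xcorr(stimulus, act, epochs, max_lag_n)
    pk <- which.max(abs(xc$mean))
    out[[name]] <- list(empty = FALSE, lags = xc$lags * frame_dt,
                        r = xc$mean, n_epochs = length(epochs),
                        peak_r = xc$mean[pk],
                        peak_lag = xc$lags[pk] * frame_dt)
  }
  class(out) <- "xcorr_result"
  out
}

#' Pairwise cross-correlogram between two activity series
#'
#' Pearson cross-correlation over the whole recording at each lag; positive
#' lags mean `b` follows `a`.
#'
#' @param a,b `activity_series` objects or numeric vectors on the same
#'   sampling grid.
#' @param frame_dt frame interval.
#' @param max_lag maximum lag in time units (default 10).
#' @return a list with `lags`, `r`, `peak_r`, `peak_lag`.
#' @export
pairwise_xcorr <- function(a, b, frame_dt, max_lag = 10) {
  xa <- if (inherits(a, "data.frame")) a$activity else a
  xb <- if (inherits(b, "data.frame")) b$activity else b
  if (length(xa) != length(xb)) stop("series length mismatch")
  max_lag_n <- round(max_lag / frame_dt)
  xc <- epoch_xcorr(xa, xb, list(seq_along(xa)), max_lag_n)
  pk <- which.max(abs(xc$mean))
  list(lags = xc$lags * frame_dt, r = xc$mean,
       peak_r = xc$mean[pk], peak_lag = xc$lags[pk] * frame_dt)
}

#' Warming/cooling phase onsets of a stimulus
#'
#' Phases are the maximal intervals of constant sign of the boxcar-smoothed
#' stimulus derivative.
#'
#' @param stimulus temperature series.
#' @param frame_dt frame interval.
#' @param smooth_window derivative smoothing window in time units
#'   (default 0.5).
#' @return a `data.frame` with `direction` ("warming"/"cooling"),
#'   `i_start`, `i_end`, `t_start`, `t_end`.
#' @export
stimulus_phases <- function(stimulus, frame_dt, smooth_window = 0.5) {
  d <- boxcar(diff(stimulus), max(1L, round(smooth_window / frame_dt)))
  sgn <- sign(d)
  sgn[sgn == 0] <- NA
  ## carry the previous sign through flat stretches
  for (i in seq_along(sgn)) {
    if (is.na(sgn[i]) && i > 1) sgn[i] <- sgn[i - 1]
  }
  sgn[is.na(sgn)] <- 1
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  data.frame(direction = ifelse(r$values > 0, "warming", "cooling"),
             i_start = starts, i_end = ends,
             t_start = starts * frame_dt, t_end = ends * frame_dt,
             stringsAsFactors = FALSE)
}

#' Probability of a supra-threshold, stimulus-congruent activity change
#'
#' For each combination of stimulus phase direction (warming/cooling) and
#' motor state (forward/reversal, assigned by majority within the phase),
#' the fraction of phase epochs whose activity change -- mean over the
#' closing `window` of the phase minus mean over the `window` preceding its
#' onset -- has the stimulus-congruent sign (positive for warming, negative
#' for cooling) and magnitude at least `magnitude_threshold`. Empty cells
#' are `NA`, not 0.
#'
#' @param activity an `activity_series` or numeric vector.
#' @param stimulus temperature series on the same grid.
#' @param states per-frame motor-state labels.
#' @param frame_dt frame interval.
#' @param magnitude_threshold response-magnitude threshold (default
#'   `0.25 * IQR(activity)`).
#' @param window averaging window in time units (default 2.5).
#' @param B bootstrap resamples for the CI (default 1000).
#' @return a `data.frame` with `direction`, `state`, `n`, `probability`,
#'   `ci_lo`, `ci_hi`.
#' @export
thermal_response_probability <- function(activity, stimulus, states,
                                         frame_dt,
                                         magnitude_threshold = NULL,
                                         window = 2.5, B = 1000) {
  act <- if (inherits(activity, "data.frame")) activity$activity else activity
  if (is.null(magnitude_threshold)) {
    magnitude_threshold <- 0.25 * stats::IQR(act)
  }
  phases <- stimulus_phases(stimulus, frame_dt)
  win_n <- max(1L, round(window / frame_dt))
  n <- length(act)
  feats <- lapply(seq_len(nrow(phases)), function(i) {
    i0 <- phases$i_start[i]
    i1 <- phases$i_end[i]
    pre_idx <- seq(max(1L, i0 - win_n), max(1L, i0 - 1L))
    post_idx <- seq(max(i0, i1 - win_n + 1L), min(i1, n))
    if (i0 == 1L) return(NULL)
    delta <- mean(act[post_idx]) - mean(act[pre_idx])
    st_maj <- round(mean(states[seq(i0, min(i1, n))]))
    list(direction = phases$direction[i], state = st_maj, delta = delta)
  })
  feats <- feats[!vapply(feats, is.null, logical(1))]
  grid <- expand.grid(direction = c("warming", "cooling"),
                      state = c("forward", "reversal"),
                      stringsAsFactors = FALSE)
  grid$n <- 0L
  grid$probability <- NA_real_
  grid$ci_lo <- NA_real_
  grid$ci_hi <- NA_real_
  for (g in seq_len(nrow(grid))) {
    st_code <- if (grid$state[g] == "forward") 1 else 0
    sel <- vapply(feats, function(f) {
      f$direction == grid$direction[g] && f$state == st_code
    }, logical(1))
    if (!any(sel)) next
    deltas <- vapply(feats[sel], function(f) f$delta, numeric(1))
    congr <- if (grid$direction[g] == "warming") {
      deltas >= magnitude_threshold
    } else {
      deltas <= -magnitude_threshold
    }
    grid$n[g] <- length(deltas)
    grid$probability[g] <- mean(congr)
    if (length(deltas) > 1) {
      ci <- bootstrap_ci(as.numeric(congr), mean, B = B)
      grid$ci_lo[g] <- ci[1]
      grid$ci_hi[g] <- ci[2]
    }
  }
  grid
}
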