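#' Construct a behavioral track
#'
#' A track is a uniformly sampled sequence of centroid positions, optionally
#' with per-frame motor-state labels (1 forward, 0 reversal), plus the unit
#' vector pointing toward the warm end of the gradient. Simulated
#' trajectories carry the warm axis `c(1, 0)`; the plate assay's gradient
#' runs along the negative x axis, i.e. `warm_axis = c(-1, 0)`, which
#' recovers the classical `-vx/|v|` bias definition.
#'
#' @param time strictly increasing, uniformly spaced time stamps.
#' @param x,y centroid positions.
#' @param motor_state optional per-frame labels (1 forward / 0 reversal).
#' @param warm_axis unit vector toward warm (default `c(1, 0)`).
#' @return a `data.frame` of class `track`.
#' @export
as_track <- function(time, x, y, motor_state = NULL, warm_axis = c(1, 0)) {
  stopifnot(length(time) == length(x), length(x) == length(y))
  if (length(time) >= 2) {
    dts <- diff(time)
    if (any(dts <= 0)) stop("time must be strictly increasing")
    if (diff(range(dts)) > 1e-6 * mean(dts)) {
      stop("time must be uniformly sampled")
    }
  }
  if (!is.null(motor_state) && length(motor_state) != length(x)) {
    stop("motor_state must match positions in length")
  }
  nw <- sqrt(sum(warm_axis^2))
  if (nw == 0) stop("warm_axis must be a nonzero vector")
  out <- data.frame(time = time, x = x, y = y)
  if (!is.null(motor_state)) out$motor_state <- as.integer(motor_state)
  attr(out, "warm_axis") <- warm_axis / nw
  class(out) <- c("track", "data.frame")
  out
}

track_warm_axis <- function(track) {
  w <- attr(track, "warm_axis")
  if (is.null(w)) c(1, 0) else w
}

#' Coerce a simulated trajectory to a track
#'
#' @param trajectory a `behavioral_trajectory` from [simulate_agent()].
#' @return a `track` keeping the motor-state labels and warm axis.
#' @export
trajectory_to_track <- function(trajectory) {
  as_track(trajectory$time, trajectory$x, trajectory$y,
           trajectory$motor_state,
           warm_axis = attr(trajectory, "warm_axis") %||% c(1, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Thermotactic bias of a track
#'
#' Per-frame bias is the velocity projection on the warm axis divided by the
#' speed, so straight motion toward warm scores +1. With the plate assay's
#' warm axis along -x this equals the classical `-vx/|v|`. Frames slower
#' than `speed_floor_frac` times the median speed are excluded from the mean
#' (near-zero speed makes the ratio unstable).
#'
#' @param track a [as_track()] object.
#' @param speed_floor_frac stationary-frame floor as a fraction of the
#'   median speed (default 0.05).
#' @return a list with `per_frame` (bias per displacement frame, `NA` where
#'   excluded) and `mean`.
#' @export
thermotactic_bias <- function(track, speed_floor_frac = 0.05) {
  stopifnot(nrow(track) >= 2)
  w <- track_warm_axis(track)
  vx <- diff(track$x)
  vy <- diff(track$y)
  sp <- sqrt(vx^2 + vy^2)
  floor_sp <- speed_floor_frac * stats::median(sp)
  ok <- sp > floor_sp & sp > 0
  if (!any(ok)) stop("no moving frames")
  bias <- rep(NA_real_, length(sp))
  bias[ok] <- (vx[ok] * w[1] + vy[ok] * w[2]) / sp[ok]
  list(per_frame = bias, mean = mean(bias[ok]))
}

#' Segment a track into run and reversal epochs
#'
#' Uses per-frame motor-state labels when present (maximal constant-label
#' intervals). Without labels, a velocity-based fallback labels a frame as a
#' reversal when the velocity projects negatively on a smoothed,
#' 3-frame-lagged heading proxy.
#'
#' @param track a [as_track()] object.
#' @param smooth_frames boxcar width (frames) for the fallback velocity
#'   smoothing (default: about 1 s worth of frames, at least 1).
#' @return a `data.frame` with one epoch per row: `state` (1 run /
#'   0 reversal), `i_start`, `i_end` (frame indices), `t_start`, `t_end`,
#'   `duration`, `direction_deg` (overall displacement angle relative to the
#'   warm axis; `NA` if the displacement is zero).
#' @export
segment_runs <- function(track, smooth_frames = NULL) {
  if (nrow(track) < 2) stop("track shorter than 2 frames")
  labels <- track$motor_state
  if (is.null(labels)) {
    labels <- infer_motor_states(track, smooth_frames)
  }
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  dt <- track$time[2] - track$time[1]
  w <- track_warm_axis(track)
  dx <- track$x[ends] - track$x[starts]
  dy <- track$y[ends] - track$y[starts]
  disp <- sqrt(dx^2 + dy^2)
  ## angle of the start-to-end displacement, measured from the warm axis
  ang <- atan2(dy * w[1] - dx * w[2], dx * w[1] + dy * w[2]) * 180 / pi
  ang[disp == 0] <- NA_real_
  data.frame(state = r$values,
             i_start = starts, i_end = ends,
             t_start = track$time[starts], t_end = track$time[ends],
             duration = (ends - starts + 1L) * dt,
             direction_deg = ang)
}

## velocity-based fallback labeling: reversal = motion against the smoothed,
## lagged heading proxy
infer_motor_states <- function(track, smooth_frames = NULL) {
  dt <- track$time[2] - track$time[1]
  if (is.null(smooth_frames)) smooth_frames <- max(1L, round(1 / dt))
  vx <- boxcar(diff(track$x), smooth_frames)
  vy <- boxcar(diff(track$y), smooth_frames)
  n <- length(vx)
  lag <- 3L
  hx <- c(rep(vx[1], lag), vx)[seq_len(n)]
  hy <- c(rep(vy[1], lag), vy)[seq_len(n)]
  proj <- vx * hx + vy * hy
  st <- ifelse(proj < 0, 0L, 1L)
  c(st[1], st)
}

boxcar <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2,
                                 circular = FALSE))
  ## fall back to the raw values where the window is incomplete
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

#' Mean run duration as a function of run direction
#'
#' Bins forward runs by the angle of their overall (start-to-end)
#' displacement relative to the warm axis, using bins of `bin_width` degrees
#' centered on the warm axis, and reports the per-bin mean duration, its
#' standard error, and the count.
#'
#' @param runs epoch table from [segment_runs()] (only `state == 1` rows are
#'   used).
#' @param bin_width angular bin width in degrees (default 30; 360 pools all
#'   runs).
#' @return a `data.frame` with `bin_center_deg`, `mean_duration`, `sem`,
#'   `n`.
#' @export
run_duration_by_direction <- function(runs, bin_width = 30) {
  runs <- runs[runs$state == 1, , drop = FALSE]
  if (any(is.na(runs$direction_deg))) {
    warning("skipping ", sum(is.na(runs$direction_deg)),
            " zero-displacement run(s)")
    runs <- runs[!is.na(runs$direction_deg), , drop = FALSE]
  }
  if (nrow(runs) == 0) stop("no runs with nonzero displacement")
  ## bins centered on the warm axis: [-w/2, w/2), [w/2, 3w/2), ...
  shift <- (runs$direction_deg + bin_width / 2) %% 360
  idx <- floor(shift / bin_width)
  centers <- idx * bin_width
  centers <- ifelse(centers >= 180, centers - 360, centers)
  agg <- split(runs$duration, centers)
  data.frame(
    bin_center_deg = as.numeric(names(agg)),
    mean_duration = vapply(agg, mean, numeric(1)),
    sem = vapply(agg, function(v) {
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1)),
    n = lengths(agg),
    row.names = NULL)
}

#' Temperature-change series and its up-gradient run histogram
#'
#' Computes the per-frame temperature derivative `dT/dt` experienced on a
#' linear gradient and, when an epoch table is supplied, a histogram of the
#' values restricted to forward runs whose overall direction points up the
#' gradient (positive warm-axis projection).
#'
#' @param track a [as_track()] object.
#' @param cT gradient slope.
#' @param runs optional epoch table from [segment_runs()].
#' @param breaks passed to [graphics::hist()] (default `"Sturges"`).
#' @return a list with `dtdt` (per displacement frame), and, when `runs` is
#'   given, `hist` (a histogram object over up-gradient forward-run frames).
#' @export
dtdt_series <- function(track, cT, runs = NULL, breaks = "Sturges") {
  dt <- track$time[2] - track$time[1]
  w <- track_warm_axis(track)
  ## temperature change per frame; on a linear gradient this is cT * dx
  proj <- diff(track$x) * w[1] + diff(track$y) * w[2]
  dtdt <- cT * proj / dt
  out <- list(dtdt = dtdt)
  if (!is.null(runs)) {
    up <- runs[runs$state == 1 & !is.na(runs$direction_deg) &
                 abs(runs$direction_deg) < 90, , drop = FALSE]
    vals <- unlist(lapply(seq_len(nrow(up)), function(i) {
      dtdt[seq(up$i_start[i], max(up$i_start[i], up$i_end[i] - 1L))]
    }))
    out$hist <- if (length(vals)) {
      graphics::hist(vals, breaks = breaks, plot = FALSE)
    } else {
      NULL
    }
    out$up_run_values <- vals
  }
  out
}

#' Detect cooling epochs in a temperature-derivative series
#'
#' Boxcar-smooths `dT/dt` and returns the maximal strictly negative
#' intervals lasting at least `min_duration`.
#'
#' @param dtdt per-frame temperature derivative.
#' @param frame_dt frame interval (time units).
#' @param min_duration minimum epoch duration (default 1 time unit).
#' @param smooth_window boxcar width in time units (default `frame_dt`, i.e.
#'   no smoothing).
#' @return a `data.frame` with `i_start`, `i_end`, `t_start`, `t_end`,
#'   `duration`, `mean_dtdt` (each strictly negative).
#' @export
detect_cooling_epochs <- function(dtdt, frame_dt, min_duration = 1,
                                  smooth_window = NULL) {
  if (is.null(smooth_window)) smooth_window <- frame_dt
  w <- max(1L, round(smooth_window / frame_dt))
  sm <- boxcar(dtdt, w)
  neg <- sm < 0
  if (!any(neg)) {
    return(data.frame(i_start = integer(0), i_end = integer(0),
                      t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), mean_dtdt = numeric(0)))
  }
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  keep <- r$values & (r$lengths * frame_dt >= min_duration)
  starts <- starts[keep]
  ends <- ends[keep]
  data.frame(i_start = starts, i_end = ends,
             t_start = starts * frame_dt, t_end = ends * frame_dt,
             duration = (ends - starts + 1L) * frame_dt,
             mean_dtdt = vapply(seq_along(starts), function(i) {
               mean(sm[seq(starts[i], ends[i])])
             }, numeric(1)))
}

#' Fraction of cooling epochs followed by run termination
#'
#' Restricts to cooling epochs that occur during forward runs and reports,
#' per cooling-duration bin, the fraction followed by a forward-to-reversal
#' transition within `response_window` after the cooling offset, with a
#' bootstrap confidence interval. Empty bins are reported as `NA`, not 0.
#'
#' @param coolings epoch table from [detect_cooling_epochs()].
#' @param states per-frame motor-state labels (1 forward / 0 reversal)
#'   aligned with the `dtdt` frames.
#' @param frame_dt frame interval.
#' @param response_window time after cooling offset in which a transition
#'   counts (default 2).
#' @param duration_bins cooling-duration bin edges (default
#'   `c(1, 3, 7, 30)`).
#' @param B bootstrap resamples for the CI (default 1000).
#' @param conf confidence level (default 0.95).
#' @return a `data.frame` with `bin_lo`, `bin_hi`, `n`, `fraction`,
#'   `ci_lo`, `ci_hi`.
#' @export
post_cooling_reversal_fraction <- function(coolings, states, frame_dt,
                                           response_window = 2,
                                           duration_bins = c(1, 3, 7, 30),
                                           B = 1000, conf = 0.95) {
  states <- as.integer(states)
  n_frames <- length(states)
  win <- max(1L, round(response_window / frame_dt))
  ## keep cooling epochs occurring during forward runs
  during_fwd <- vapply(seq_len(nrow(coolings)), function(i) {
    idx <- seq(coolings$i_start[i], min(coolings$i_end[i], n_frames))
    all(states[idx] == 1L)
  }, logical(1))
  cool <- coolings[during_fwd, , drop = FALSE]
  responded <- vapply(seq_len(nrow(cool)), function(i) {
    idx <- seq(min(cool$i_end[i] + 1L, n_frames),
               min(cool$i_end[i] + win, n_frames))
    any(states[idx] == 0L)
  }, logical(1))
  edges <- duration_bins
  out <- data.frame(bin_lo = utils::head(edges, -1),
                    bin_hi = utils::tail(edges, -1))
  out$n <- 0L
  out$fraction <- NA_real_
  out$ci_lo <- NA_real_
  out$ci_hi <- NA_real_
  for (b in seq_len(nrow(out))) {
    inbin <- cool$duration >= out$bin_lo[b] & cool$duration < out$bin_hi[b]
    out$n[b] <- sum(inbin)
    if (out$n[b] > 0) {
      r <- responded[inbin]
      out$fraction[b] <- mean(r)
      ci <- bootstrap_ci(as.numeric(r), mean, B = B, level = conf)
      out$ci_lo[b] <- ci[1]
      out$ci_hi[b] <- ci[2]
    }
  }
  out
}

#' Fraction of forward runs that ended after a period of cooling
#'
#' A forward run counts when some cooling epoch overlaps the
#' `lookback_window` preceding the run's end.
#'
#' @param runs epoch table from [segment_runs()].
#' @param coolings epoch table from [detect_cooling_epochs()] on the same
#'   time base.
#' @param lookback_window time before run end searched for cooling
#'   (default 2).
#' @return the fraction (scalar); errors when there are no forward runs.
#' @export
run_end_after_cooling_fraction <- function(runs, coolings,
                                           lookback_window = 2) {
  fwd <- runs[runs$state == 1, , drop = FALSE]
  if (nrow(fwd) == 0) stop("no forward runs")
  if (nrow(coolings) == 0) return(0)
  hit <- vapply(seq_len(nrow(fwd)), function(i) {
    lo <- fwd$t_end[i] - lookback_window
    any(coolings$t_end >= lo & coolings$t_start <= fwd$t_end[i])
  }, logical(1))
  mean(hit)
}
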