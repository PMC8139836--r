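#' Configuration for the synthetic-data generators
#'
#' The generators emit stimuli, two-channel fluorescence traces and
#' behavioral tracks with the statistical structure the analysis modules
#' assume, together with the generating ground truth, so every pipeline has
#' a parameter-recovery test that needs no external data.
#'
#' The `mode` flag controls the corollary-discharge gating of the
#' interneuron archetype: in `"wildtype"` mode the AIY stimulus response is
#' present only during forward runs (and the behavioral run-termination
#' hazard is only mildly raised by cooling); in `"ablated"` mode the gate is
#' removed -- AIY tracks the stimulus in every motor state, the
#' reversal-neuron bimodality is reduced, and the behavioral hazard under
#' cooling is strongly increased, emulating the loss of the feedback signal.
#'
#' @param seed RNG seed.
#' @param frame_dt frame interval in seconds (default 0.83, about 1.2
#'   volumes/s).
#' @param duration recording duration in seconds (default 600).
#' @param stimulus_type `"sinusoid"` or `"constant"`.
#' @param stimulus_amplitude sinusoid amplitude, temperature units
#'   (default 1).
#' @param stimulus_period sinusoid period in seconds (default 30).
#' @param run_mean,rev_mean mean run and reversal dwell times in seconds
#'   (default 20 and 5; exponential dwells truncated at one frame).
#' @param sensory_gain activity response per unit `dT/dt` (default 2).
#' @param motor_gain activity step between motor states (default 1).
#' @param mode `"wildtype"` or `"ablated"` (see Details).
#' @param noise_sd multiplicative channel noise sd (default 0.05).
#' @param kernel_tau calcium-kernel time constant in seconds (default 1).
#' @param channel_scale mean fluorescence counts per channel (default 100).
#' @param cT gradient slope for behavioral tracks, temperature units per
#'   unit length (default 0.1).
#' @param track_speed track speed, unit length per second (default 1).
#' @param heading_jitter_sd sd of the per-frame Gaussian heading jitter in
#'   degrees applied within bouts of synthetic tracks (default 15); real
#'   trajectories weave, so the sensed temperature fluctuates within runs.
#' @param cooling_hazard_mult multiplier on the run-termination hazard while
#'   cooling; default 2 in wildtype mode, 6 in ablated mode; 1 removes all
#'   direction dependence.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1, frame_dt = 0.83, duration = 600,
                         stimulus_type = c("sinusoid", "constant"),
                         stimulus_amplitude = 1, stimulus_period = 30,
                         run_mean = 20, rev_mean = 5,
                         sensory_gain = 2, motor_gain = 1,
                         mode = c("wildtype", "ablated"),
                         noise_sd = 0.05, kernel_tau = 1,
                         channel_scale = 100, cT = 0.1, track_speed = 1,
                         heading_jitter_sd = 15,
                         cooling_hazard_mult = NULL) {
  stimulus_type <- match.arg(stimulus_type)
  mode <- match.arg(mode)
  stopifnot(frame_dt > 0, duration > 0, run_mean > frame_dt,
            rev_mean > frame_dt, noise_sd >= 0, kernel_tau > 0,
            channel_scale > 0, track_speed > 0)
  if (is.null(cooling_hazard_mult)) {
    cooling_hazard_mult <- if (mode == "wildtype") 2 else 6
  }
  structure(list(seed = seed, frame_dt = frame_dt, duration = duration,
                 stimulus_type = stimulus_type,
                 stimulus_amplitude = stimulus_amplitude,
                 stimulus_period = stimulus_period,
                 run_mean = run_mean, rev_mean = rev_mean,
                 sensory_gain = sensory_gain, motor_gain = motor_gain,
                 mode = mode, noise_sd = noise_sd, kernel_tau = kernel_tau,
                 channel_scale = channel_scale, cT = cT,
                 track_speed = track_speed,
                 heading_jitter_sd = heading_jitter_sd,
                 cooling_hazard_mult = cooling_hazard_mult),
            class = "synth_config")
}

#' Synthetic temperature stimulus
#'
#' Constant or sinusoidal temperature series on the configured frame grid.
#' Deterministic (no RNG involved).
#'
#' @param config a [synth_config()].
#' @return a `data.frame` with `time` and `temperature`.
#' @export
make_stimulus <- function(config) {
  tt <- seq(0, config$duration, by = config$frame_dt)
  temp <- if (config$stimulus_type == "constant") {
    rep(0, length(tt))
  } else {
    config$stimulus_amplitude * sin(2 * pi * tt / config$stimulus_period)
  }
  data.frame(time = tt, temperature = temp)
}

## alternating exponential dwells, truncated at one frame
sample_bouts <- function(n_frames, frame_dt, run_mean, rev_mean,
                         start_state = 1L) {
  states <- integer(0)
  st <- start_state
  bouts <- list()
  while (length(states) < n_frames) {
    mean_dwell <- if (st == 1L) run_mean else rev_mean
    dur <- max(1L, round(stats::rexp(1, 1 / mean_dwell) / frame_dt))
    dur <- min(dur, n_frames - length(states))
    bouts[[length(bouts) + 1L]] <- list(state = st,
                                        i_start = length(states) + 1L,
                                        i_end = length(states) + dur)
    states <- c(states, rep(st, dur))
    st <- 1L - st
  }
  list(states = states, bouts = do.call(rbind, lapply(bouts, as.data.frame)))
}

#' Synthetic run/reversal motor-state sequence
#'
#' Alternating two-state sequence with exponential dwell times (truncated at
#' one frame), starting in a forward run.
#'
#' @param config a [synth_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return a list with `states` (1 forward / 0 reversal per frame), `time`,
#'   and `ground_truth` (the bout table with onset frames and the
#'   generating dwell means).
#' @export
make_motor_states <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, config$duration, by = config$frame_dt)
  sb <- sample_bouts(length(tt), config$frame_dt, config$run_mean,
                     config$rev_mean)
  gt <- list(bouts = sb$bouts,
             run_onsets = tt[sb$bouts$i_start[sb$bouts$state == 1]],
             reversal_onsets = tt[sb$bouts$i_start[sb$bouts$state == 0]],
             run_mean = config$run_mean, rev_mean = config$rev_mean)
  list(states = sb$states, time = tt, ground_truth = gt)
}

## first-order exponential (calcium indicator) smoothing
calcium_kernel <- function(x, frame_dt, tau) {
  a <- exp(-frame_dt / tau)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive",
                           init = x[1]))
}

#' Synthetic two-channel neural traces for the circuit archetypes
#'
#' Builds latent activities for four archetypes -- `AFD` (pure phase-locked
#' thermosensor), `AIY` (motor-state step plus a stimulus response gated by
#' the forward state; in ablated mode both the motor term and the gate are
#' lost and AIY tracks the stimulus in every state), `AVA`
#' (reversal-active; bimodality reduced and a stimulus leak added in ablated
#' mode) and `RME` (forward-active) -- smooths them with an exponential
#' calcium kernel, and renders each as green/red fluorescence channels with
#' independent multiplicative noise.
#'
#' @param states per-frame motor states from [make_motor_states()].
#' @param stimulus stimulus table from [make_stimulus()] on the same grid.
#' @param config a [synth_config()].
#' @param seed RNG seed (default `config$seed + 1`, so the channel noise is
#'   independent of the bout sampling).
#' @return a list with `traces` (named list of `data.frame`s with `time`,
#'   `green`, `red`, `motor_state`) and `ground_truth` (latent signals,
#'   gains and gate mode).
#' @export
make_neural_traces <- function(states, stimulus, config,
                               seed = if (is.null(config$seed)) NULL else
                                 config$seed + 1L) {
  stopifnot(length(states) == nrow(stimulus))
  if (!is.null(seed)) set.seed(seed)
  dt <- config$frame_dt
  dTdt <- c(0, diff(stimulus$temperature)) / dt
  stim_term <- config$sensory_gain * dTdt
  M <- as.numeric(states)
  ## wildtype: AIY carries the motor state and senses only while running
  ## forward; ablated: the corollary discharge is gone, so AIY loses the
  ## motor term and tracks the stimulus in every state
  latents <- list(
    AFD = stim_term,
    AIY = if (config$mode == "wildtype") {
      config$motor_gain * M + M * stim_term
    } else {
      stim_term
    },
    AVA = if (config$mode == "wildtype") {
      config$motor_gain * (1 - M)
    } else {
      0.5 * config$motor_gain * (1 - M) + 0.5 * stim_term
    },
    RME = config$motor_gain * M)
  smoothed <- lapply(latents, calcium_kernel, frame_dt = dt,
                     tau = config$kernel_tau)
  traces <- lapply(smoothed, function(lat) {
    eg <- stats::rnorm(length(lat), 0, config$noise_sd)
    er <- stats::rnorm(length(lat), 0, config$noise_sd)
    green <- config$channel_scale * pmax(1 + lat, 0.05) * pmax(1 + eg, 0.05)
    red <- config$channel_scale * pmax(1 + er, 0.05)
    data.frame(time = stimulus$time, green = green, red = red,
               motor_state = states)
  })
  list(traces = traces,
       ground_truth = list(latents = smoothed, raw_latents = latents,
                           mode = config$mode,
                           sensory_gain = config$sensory_gain,
                           motor_gain = config$motor_gain))
}

#' One-call synthetic imaging dataset
#'
#' Stimulus, motor states and archetype traces from a single config.
#'
#' @param config a [synth_config()].
#' @return a list with `stimulus`, `states`, `time`, `traces`,
#'   `ground_truth`.
#' @export
synth_dataset <- function(config) {
  stim <- make_stimulus(config)
  ms <- make_motor_states(config)
  tr <- make_neural_traces(ms$states, stim, config)
  list(stimulus = stim, states = ms$states, time = ms$time,
       traces = tr$traces,
       ground_truth = c(ms$ground_truth, tr$ground_truth))
}

#' Synthetic behavioral tracks on a linear gradient
#'
#' Constant-speed random-walk tracks with run/reversal labels following the
#' standard heading rules (180 degree flip into reversals, fresh uniform
#' heading at run onset) plus Gaussian per-frame heading jitter within
#' bouts, emulating the weaving of real trajectories -- without it the
#' temperature change could never reverse sign inside a run. The per-frame
#' run-termination hazard is `frame_dt / run_mean`, multiplied by
#' `cooling_hazard_mult` while the animal experiences cooling (moves down
#' the gradient) -- mildly in wildtype mode, strongly in ablated mode --
#' which yields direction-dependent run durations and the post-cooling
#' reversal contrast between the two modes.
#'
#' @param config a [synth_config()].
#' @param n number of tracks.
#' @param seed master RNG seed (default `config$seed`).
#' @return a list with `tracks` (list of [as_track()] objects with labels)
#'   and `ground_truth` (per-track bout tables and the hazard parameters).
#' @export
make_tracks <- function(config, n, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n_frames <- length(seq(0, config$duration, by = config$frame_dt))
  dt <- config$frame_dt
  base_h_run <- dt / config$run_mean
  h_rev <- dt / config$rev_mean
  tracks <- vector("list", n)
  gt_bouts <- vector("list", n)
  for (tr in seq_len(n)) {
    th <- stats::runif(1, -pi, pi)
    st <- 1L
    x <- numeric(n_frames)
    y <- numeric(n_frames)
    states <- integer(n_frames)
    cx <- 0
    cy <- 0
    jitter_rad <- config$heading_jitter_sd * pi / 180
    for (i in seq_len(n_frames)) {
      ## worms weave: the heading wanders within a bout, so the sensed
      ## temperature fluctuates even during a straight-ish run
      th <- wrap_rad(th + stats::rnorm(1, 0, jitter_rad))
      dx <- config$track_speed * dt * cos(th)
      cooling <- dx < 0
      if (st == 1L) {
        h <- base_h_run * if (cooling) config$cooling_hazard_mult else 1
        if (stats::runif(1) < h) {
          st <- 0L
          th <- wrap_rad(th + pi)
          dx <- config$track_speed * dt * cos(th)
        }
      } else {
        if (stats::runif(1) < h_rev) {
          st <- 1L
          th <- stats::runif(1, -pi, pi)
          dx <- config$track_speed * dt * cos(th)
        }
      }
      cx <- cx + dx
      cy <- cy + config$track_speed * dt * sin(th)
      x[i] <- cx
      y[i] <- cy
      states[i] <- st
    }
    tt <- seq_len(n_frames) * dt
    tracks[[tr]] <- as_track(tt, x, y, states, warm_axis = c(1, 0))
    gt_bouts[[tr]] <- segment_runs(tracks[[tr]])
  }
  list(tracks = tracks,
       ground_truth = list(bouts = gt_bouts,
                           run_mean = config$run_mean,
                           rev_mean = config$rev_mean,
                           cooling_hazard_mult = config$cooling_hazard_mult,
                           mode = config$mode, cT = config$cT))
}
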