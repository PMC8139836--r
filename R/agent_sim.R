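#' Configuration of the navigating agent
#'
#' The agent moves at constant speed on an unbounded plane carrying a linear
#' thermal gradient `T(x) = cT * x` (warm toward +x). Its thermosensory input
#' is the temperature change over the last `sense_lag` steps,
#' `Iinput(t) = cT * (x(t) - x(t - sense_lag))`, plus Gaussian sensory noise,
#' and it is fed (scaled by the circuit's `alpha`) into the reduced circuit
#' model, whose motor-command sign sets the run/reversal state.
#'
#' Defaults are calibrated so that a straight run along the gradient delivers
#' an effective drive `alpha * cT * speed * step_dt = 1.2`, well outside the
#' bistable input band (|drive| < ~0.37) of the calibrated positive-feedback
#' circuit -- so sustained cooling can break the forward latch -- while the
#' per-step sensory noise (0.15 after `alpha`) stays inside it, so the latch
#' filters noise. See the package vignette for the calibration rationale.
#'
#' @param cT gradient slope, temperature units per unit length (default
#'   0.02).
#' @param speed locomotion speed, distance per time unit (default 1).
#' @param step_dt duration of one behavioral step (default 1).
#' @param sense_lag temperature-differencing lag in steps (>= 1, default 1).
#' @param tmax number of behavioral steps (default 2000).
#' @param noise_sd sd of the per-step Gaussian sensory noise added to
#'   `Iinput`, in input units before `alpha` (default 0.0025).
#' @param seed optional RNG seed stored in the config and used by
#'   [simulate_agent()] when no explicit seed is given.
#' @param circuit a [circuit_params()] object (default: calibrated positive
#'   feedback with `alpha = 60`).
#' @return an object of class `agent_config`.
#' @export
agent_config <- function(cT = 0.02, speed = 1, step_dt = 1, sense_lag = 1,
                         tmax = 2000, noise_sd = 0.0025, seed = NULL,
                         circuit = circuit_params(wfb = 1, alpha = 60)) {
  stopifnot(is.finite(cT), speed > 0, step_dt > 0, sense_lag >= 1,
            tmax > 0, noise_sd >= 0)
  validate_circuit_params(circuit)
  structure(list(cT = cT, speed = speed, step_dt = step_dt,
                 sense_lag = as.integer(sense_lag), tmax = as.integer(tmax),
                 noise_sd = noise_sd, seed = seed, circuit = circuit),
            class = "agent_config")
}

#' Temperature on the linear gradient
#'
#' `T(x) = cT * x`; the arena is unbounded and the gradient linear
#' everywhere.
#'
#' @param x position(s) along the gradient axis.
#' @param cT gradient slope.
#' @return temperature value(s).
#' @export
temperature_at <- function(x, cT) cT * x

#' Sensed thermosensory input from a position history
#'
#' `Iinput(t) = cT * (x(t) - x(t - lag))`; positions earlier than the start
#' of the history are taken at the starting position, so the input is 0
#' before one full lag of history exists.
#'
#' @param x numeric vector of x positions, oldest first; the last element is
#'   the current position.
#' @param cT gradient slope.
#' @param lag differencing lag in samples (>= 1).
#' @return the sensed input current (scalar).
#' @export
sensed_input <- function(x, cT, lag = 1) {
  stopifnot(length(x) >= 1, lag >= 1)
  n <- length(x)
  xlag <- if (n - lag >= 1) x[n - lag] else x[1]
  cT * (x[n] - xlag)
}

#' Motor state from the motor-command activity
#'
#' Forward (1) if `V2 > 0`, reversal (0) if `V2 < 0`, previous state if
#' `V2 == 0`.
#'
#' @param V2 motor-command activity (scalar or vector, applied sequentially).
#' @param previous state before the first element (default forward).
#' @return integer state(s), same length as `V2`.
#' @export
motor_state_of <- function(V2, previous = 1L) {
  motor_states_from_v2(V2, init_state = previous)
}

#' Heading update rule at motor-state transitions
#'
#' Heading is constant within a bout; a run-to-reversal transition negates
#' the heading vector (180 degree turn); a reversal-to-run transition draws a
#' fresh heading uniformly on \eqn{[-180, 180)} degrees.
#'
#' @param theta_prev previous heading, degrees in \eqn{[-180, 180)}.
#' @param M_now,M_prev current and previous motor state (1 forward,
#'   0 reversal).
#' @return new heading in degrees (consumes one uniform deviate when a run
#'   starts).
#' @export
update_heading <- function(theta_prev, M_now, M_prev) {
  if (M_now == M_prev) return(theta_prev)
  if (M_now == 0) {
    th <- theta_prev + 180
    return(th - 360 * floor((th + 180) / 360))
  }
  stats::runif(1, -180, 180)
}

#' Simulate one navigating agent
#'
#' Starts at the origin in a forward run, heading drawn uniformly, circuit
#' state `(V1, V2) = (1, 1)`. Each behavioral step senses the temperature
#' change, integrates the circuit by fixed-step RK4 over `step_dt`, updates
#' the motor state by the sign rule, applies the heading rule, and moves
#' `speed * step_dt` along the heading. Fully reproducible given the seed.
#'
#' @param config an [agent_config()].
#' @param seed RNG seed (defaults to `config$seed`; if both are `NULL` the
#'   current RNG state is used).
#' @param engine `"cpp"` (compiled stepper, default) or `"r"` (reference
#'   implementation; consumes the RNG identically).
#' @return a `data.frame` of class `behavioral_trajectory` with columns
#'   `time`, `x`, `y`, `heading_deg`, `motor_state`, `temperature`,
#'   `Iinput`, `V1`, `V2`, and attribute `warm_axis = c(1, 0)`.
#' @export
simulate_agent <- function(config, seed = NULL,
                           engine = c("cpp", "r")) {
  stopifnot(inherits(config, "agent_config"))
  engine <- match.arg(engine)
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  p <- config$circuit
  nsub <- max(1L, ceiling(config$step_dt / (p$tau1 / 20) - 1e-9))
  if (engine == "cpp") {
    par <- c(p$tau1, p$tau2, p$gL1, p$gL2, p$wfb, p$w21, p$k1, p$k2, p$k3,
             p$beta1, p$beta2, p$beta2p, p$gamma1, p$gamma2, p$C1, p$C2,
             if (p$form == "odd") 0 else 1)
    res <- agent_sim_cpp(config$tmax, config$step_dt, config$speed,
                         config$cT, config$sense_lag, config$noise_sd,
                         p$alpha, nsub, par)
  } else {
    res <- agent_sim_r(config, nsub)
  }
  out <- data.frame(time = seq_len(config$tmax) * config$step_dt,
                    x = res$x, y = res$y, heading_deg = res$heading_deg,
                    motor_state = res$motor_state,
                    temperature = res$temperature, Iinput = res$Iinput,
                    V1 = res$V1, V2 = res$V2)
  attr(out, "warm_axis") <- c(1, 0)
  attr(out, "config") <- config
  class(out) <- c("behavioral_trajectory", "data.frame")
  out
}

## pure-R reference stepper; mirrors the RNG consumption of the C++ engine
agent_sim_r <- function(config, nsub) {
  p <- config$circuit
  h <- config$step_dt / nsub
  tmax <- config$tmax
  x <- numeric(tmax); y <- numeric(tmax); heading <- numeric(tmax)
  motor <- integer(tmax); iinput <- numeric(tmax)
  v1s <- numeric(tmax); v2s <- numeric(tmax)
  xhist <- numeric(tmax)
  th <- stats::runif(1, -pi, pi)
  state <- c(1, 1); M <- 1L; cx <- 0; cy <- 0
  for (t in seq_len(tmax)) {
    lag_idx <- t - 1L - config$sense_lag
    xlag <- if (lag_idx < 1) 0 else xhist[lag_idx]
    I <- config$cT * (cx - xlag) + stats::rnorm(1) * config$noise_sd
    for (j in seq_len(nsub)) state <- rk4_step(state, I, p, h)
    if (!all(is.finite(state))) stop("non-finite circuit state at step ", t)
    Mnew <- if (state[2] > 0) 1L else if (state[2] < 0) 0L else M
    if (Mnew != M) {
      th <- if (Mnew == 0L) wrap_rad(th + pi) else stats::runif(1, -pi, pi)
    }
    M <- Mnew
    cx <- cx + config$speed * config$step_dt * cos(th)
    cy <- cy + config$speed * config$step_dt * sin(th)
    xhist[t] <- cx
    x[t] <- cx; y[t] <- cy; heading[t] <- th * 180 / pi
    motor[t] <- M; iinput[t] <- I; v1s[t] <- state[1]; v2s[t] <- state[2]
  }
  list(x = x, y = y, heading_deg = heading, motor_state = motor,
       temperature = config$cT * x, Iinput = iinput, V1 = v1s, V2 = v2s)
}

wrap_rad <- function(th) {
  th <- (th + pi) %% (2 * pi)
  th - pi
}

#' Simulate a population of independent agents
#'
#' Per-agent seeds are derived deterministically from the master seed, so the
#' population is reproducible and each agent independent.
#'
#' @param n number of agents (>= 1).
#' @param config an [agent_config()].
#' @param seed master seed.
#' @return a list of `behavioral_trajectory` objects with attribute
#'   `agent_seeds`.
#' @export
simulate_population <- function(n, config, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  agent_seeds <- sample.int(.Machine$integer.max - 1L, n)
  out <- lapply(agent_seeds, function(s) simulate_agent(config, seed = s))
  attr(out, "agent_seeds") <- agent_seeds
  attr(out, "master_seed") <- seed
  out
}
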