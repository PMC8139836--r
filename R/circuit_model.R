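#' Parameters of the reduced two-variable thermotaxis circuit
#'
#' Constructs the parameter set of the reduced circuit model
#' \deqn{\tau_1 \dot V_1 = -g_{L1} V_1 + \alpha I_{input} + F_{12}(V_2) + C_1}
#' \deqn{\tau_2 \dot V_2 = -g_{L2} V_2 + F_{21}(V_1) + C_2}
#' where \eqn{V_1} is the activity of the first-layer interneuron (AIY) and
#' \eqn{V_2} the activity of the motor command module. The corollary-discharge
#' feedback is \eqn{F_{12}(V_2) = w_{fb}\,\sigma(k_1 (V_2 - \beta_1))} with
#' \eqn{\sigma} the logistic function, and the motor drive is, in the default
#' odd-symmetric form,
#' \eqn{F_{21}(V_1) = w_{21}[\gamma_1 \sigma(k_2 (V_1-\beta_2)) -
#' \gamma_2 \sigma(-k_3 (V_1-\beta_2'))]},
#' which contrasts a forward-promoting (AVB-like) and a reversal-promoting
#' (AVA-like) premotor pool and reduces to a tanh switch when the two pools
#' are symmetric. The printed literal form (both sigmoids with the same sign
#' convention) is available via `form = "literal"`; with symmetric pool
#' parameters it cancels identically, which is why the odd-symmetric form is
#' the default.
#'
#' Two presets are shipped. `"calibrated"` (default) keeps every published
#' value except the motor-drive inflection points, which are moved from 1.5 to
#' 1.0 -- the midpoint of the interneuron nullcline range under positive
#' feedback -- restoring the intended three-intersection bistable geometry.
#' `"literal"` uses the published table verbatim (and is monostable).
#'
#' @param wfb feedback gain; the model compares -1 (negative feedback),
#'   0 (no feedback) and +1 (positive feedback, corollary discharge).
#' @param preset `"calibrated"` (bistable, default) or `"literal"`.
#' @param alpha sensory coupling \eqn{\alpha = w_0 R / g_{L1}} multiplying the
#'   input current.
#' @param form `"odd"` (default) or `"literal"` motor-drive interpretation.
#' @param tau1,tau2 time constants (> 0), in the model's arbitrary time unit.
#' @param gL1,gL2 leak conductances (> 0).
#' @param w21 motor-drive weight.
#' @param k1,k2,k3 sigmoid steepness values (> 0).
#' @param beta1,beta2,beta2p sigmoid inflection points; `beta2`/`beta2p`
#'   default to 1.0 under the calibrated preset, 1.5 under the literal one.
#' @param gamma1,gamma2 sigmoid heights (>= 0).
#' @param C1,C2 constant offsets collecting the resting potentials.
#' @return an object of class `circuit_params` (a named list).
#' @seealso [nullclines()], [find_fixed_points()], [integrate_circuit()]
#' @examples
#' p <- circuit_params(wfb = 1)
#' find_fixed_points(p)
#' @export
circuit_params <- function(wfb = 1, preset = c("calibrated", "literal"),
                           alpha = 1, form = c("odd", "literal"),
                           tau1 = 2 / 3, tau2 = 2 / 3, gL1 = 1, gL2 = 1,
                           w21 = 1, k1 = 15, k2 = 5, k3 = 5,
                           beta1 = 0, beta2 = NULL, beta2p = NULL,
                           gamma1 = 1, gamma2 = 1, C1 = 0.5, C2 = 0) {
  preset <- match.arg(preset)
  form <- match.arg(form)
  b2_default <- if (preset == "calibrated") 1.0 else 1.5
  if (is.null(beta2)) beta2 <- b2_default
  if (is.null(beta2p)) beta2p <- b2_default
  p <- list(tau1 = tau1, tau2 = tau2, gL1 = gL1, gL2 = gL2, alpha = alpha,
            wfb = wfb, w21 = w21, k1 = k1, k2 = k2, k3 = k3,
            beta1 = beta1, beta2 = beta2, beta2p = beta2p,
            gamma1 = gamma1, gamma2 = gamma2, C1 = C1, C2 = C2,
            form = form, preset = preset)
  validate_circuit_params(p)
  structure(p, class = "circuit_params")
}

validate_circuit_params <- function(p) {
  num <- c("tau1", "tau2", "gL1", "gL2", "alpha", "wfb", "w21",
           "k1", "k2", "k3", "beta1", "beta2", "beta2p",
           "gamma1", "gamma2", "C1", "C2")
  vals <- unlist(p[num])
  if (!all(is.finite(vals))) {
    stop("non-finite circuit parameter(s): ",
         paste(num[!is.finite(vals)], collapse = ", "))
  }
  pos <- c("tau1", "tau2", "gL1", "gL2", "k1", "k2", "k3")
  if (any(unlist(p[pos]) <= 0)) {
    stop("parameters ", paste(pos, collapse = ", "), " must be > 0")
  }
  if (p$gamma1 < 0 || p$gamma2 < 0) stop("gamma1, gamma2 must be >= 0")
  invisible(p)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf("<circuit_params> preset=%s form=%s wfb=%+g alpha=%g\n",
              x$preset, x$form, x$wfb, x$alpha))
  cat(sprintf("  tau=(%.4g, %.4g) gL=(%g, %g) w21=%g k=(%g, %g, %g)\n",
              x$tau1, x$tau2, x$gL1, x$gL2, x$w21, x$k1, x$k2, x$k3))
  cat(sprintf("  beta=(%g, %g, %g) gamma=(%g, %g) C=(%g, %g)\n",
              x$beta1, x$beta2, x$beta2p, x$gamma1, x$gamma2, x$C1, x$C2))
  invisible(x)
}

#' Parameters of the unreduced three-neuron model
#'
#' The full model adds the thermosensory neuron (AFD) as a leaky integrator
#' \eqn{\tau_0 \dot V_0 = -g_{L0}(V_0 - V_{L0}) + I_{input} R}; the reduction
#' replaces it by its steady state (see [afd_steady_state()]).
#'
#' @param tau0 AFD time constant (> 0).
#' @param gL0 AFD leak conductance (> 0).
#' @param VL0,VL1,VL2 resting potentials.
#' @param R input resistance (> 0).
#' @param w0 AFD-to-interneuron weight.
#' @return an object of class `full_model_params`.
#' @export
full_model_params <- function(tau0 = 1, gL0 = 1, VL0 = 0, VL1 = 0.5,
                              VL2 = 0, R = 1, w0 = 1) {
  if (!all(is.finite(c(tau0, gL0, VL0, VL1, VL2, R, w0)))) {
    stop("non-finite full-model parameter")
  }
  if (tau0 <= 0 || gL0 <= 0 || R <= 0) stop("tau0, gL0, R must be > 0")
  structure(list(tau0 = tau0, gL0 = gL0, VL0 = VL0, VL1 = VL1, VL2 = VL2,
                 R = R, w0 = w0),
            class = "full_model_params")
}

logistic <- function(z) 1 / (1 + exp(-z))

#' Corollary-discharge feedback drive onto the interneuron
#'
#' \eqn{F_{12}(V_2) = w_{fb}\, \sigma(k_1 (V_2 - \beta_1))}, bounded in
#' magnitude by `|wfb|`.
#'
#' @param V2 motor-command activity (vectorized).
#' @param params a [circuit_params()] object.
#' @return the feedback drive, same length as `V2`.
#' @export
feedback_drive <- function(V2, params) {
  if (!all(is.finite(V2))) stop("non-finite V2")
  params$wfb * logistic(params$k1 * (V2 - params$beta1))
}

#' Motor drive from the interneuron onto the motor command module
#'
#' Default odd-symmetric form
#' \eqn{w_{21}[\gamma_1 \sigma(k_2 (V_1 - \beta_2)) -
#' \gamma_2 \sigma(-k_3 (V_1 - \beta_2'))]}: positive values favor forward
#' runs, negative values reversals. `form = "literal"` evaluates both pool
#' sigmoids with the printed sign convention
#' \eqn{w_{21}[\gamma_1 \sigma(k_2 (V_1-\beta_2)) -
#' \gamma_2 \sigma(k_3 (V_1-\beta_2'))]}, which cancels identically when the
#' two pools share parameters.
#'
#' @param V1 interneuron activity (vectorized).
#' @param params a [circuit_params()] object.
#' @return the motor drive, same length as `V1`.
#' @export
motor_drive <- function(V1, params) {
  if (!all(is.finite(V1))) stop("non-finite V1")
  fwd <- params$gamma1 * logistic(params$k2 * (V1 - params$beta2))
  rev_sign <- if (params$form == "odd") -1 else 1
  rev <- params$gamma2 * logistic(rev_sign * params$k3 * (V1 - params$beta2p))
  params$w21 * (fwd - rev)
}

## analytic derivatives of the synaptic drives, used by the Jacobian
feedback_drive_deriv <- function(V2, params) {
  s <- logistic(params$k1 * (V2 - params$beta1))
  params$wfb * params$k1 * s * (1 - s)
}

motor_drive_deriv <- function(V1, params) {
  s2 <- logistic(params$k2 * (V1 - params$beta2))
  rev_sign <- if (params$form == "odd") -1 else 1
  s3 <- logistic(rev_sign * params$k3 * (V1 - params$beta2p))
  d_fwd <- params$gamma1 * params$k2 * s2 * (1 - s2)
  d_rev <- params$gamma2 * rev_sign * params$k3 * s3 * (1 - s3)
  params$w21 * (d_fwd - d_rev)
}

#' Steady-state activity of the thermosensory neuron
#'
#' The reduction sets AFD to its steady state
#' \eqn{V_0 = V_{L0} + I_{input} R / g_{L0}}.
#'
#' @param Iinput input current (vectorized).
#' @param full a [full_model_params()] object.
#' @return steady-state AFD activity.
#' @export
afd_steady_state <- function(Iinput, full) {
  full$VL0 + Iinput * full$R / full$gL0
}

#' Time derivatives of the reduced circuit
#'
#' @param state numeric vector `c(V1, V2)`.
#' @param Iinput input current (scalar).
#' @param params a [circuit_params()] object.
#' @return numeric vector `c(dV1dt, dV2dt)`.
#' @export
circuit_derivs <- function(state, Iinput, params) {
  V1 <- state[[1]]
  V2 <- state[[2]]
  dV1 <- (-params$gL1 * V1 + params$alpha * Iinput +
            feedback_drive(V2, params) + params$C1) / params$tau1
  dV2 <- (-params$gL2 * V2 + motor_drive(V1, params) + params$C2) / params$tau2
  c(dV1, dV2)
}

## one classical RK4 step of the autonomous-within-step system
rk4_step <- function(state, Iinput, params, h) {
  k1 <- circuit_derivs(state, Iinput, params)
  k2 <- circuit_derivs(state + h / 2 * k1, Iinput, params)
  k3 <- circuit_derivs(state + h / 2 * k2, Iinput, params)
  k4 <- circuit_derivs(state + h * k3, Iinput, params)
  state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Build a uniformly sampled input series
#'
#' @param values input current per sample.
#' @param dt sample interval (> 0), in model time units.
#' @return an object of class `input_series`.
#' @export
input_series <- function(values, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be > 0")
  if (!all(is.finite(values))) stop("non-finite input values")
  structure(list(values = as.numeric(values), dt = dt), class = "input_series")
}

#' Oscillating-input demonstration stimulus
#'
#' A sinusoid of effective amplitude `amplitude` (in units of
#' \eqn{\alpha I_{input}}) and period `period`, plus Gaussian sensory noise of
#' sd `noise_sd` drawn independently per sample. The noise stands for the
#' fluctuations that ride on any real thermosensory drive; without it the
#' response of every gain setting is strictly periodic and no persistence
#' contrast can exist (see the package vignette).
#'
#' @param amplitude sinusoid amplitude (default 0.25, inside the bistable
#'   input band of the calibrated positive-feedback model, |I| < ~0.37).
#' @param period sinusoid period in time units (default 40).
#' @param duration total duration (default 4000).
#' @param dt sampling interval (default 1).
#' @param noise_sd sensory noise sd per sample (default 0.15).
#' @return an `input_series`.
#' @export
oscillating_input <- function(amplitude = 0.25, period = 40, duration = 4000,
                              dt = 1, noise_sd = 0.15) {
  tt <- seq(0, duration, by = dt)
  vals <- amplitude * sin(2 * pi * tt / period) +
    stats::rnorm(length(tt), 0, noise_sd)
  input_series(vals, dt)
}

#' Integrate the reduced circuit with fixed-step RK4
#'
#' The input is held constant within each input sample (zero-order hold) and
#' the state advanced by classical fourth-order Runge-Kutta substeps of size
#' `dt_substep` (default `min(input$dt, tau1/20)`). The motor state is 1
#' (forward) where `V2 > 0`, 0 (reversal) where `V2 < 0`, and keeps its
#' previous value where `V2 == 0` (initially forward).
#'
#' @param init numeric `c(V1, V2)` initial state; the published simulations
#'   start from `c(1, 1)`.
#' @param input an [input_series()].
#' @param params a [circuit_params()] object.
#' @param dt_substep RK4 substep; must not exceed `input$dt`.
#' @return a `data.frame` of class `circuit_trajectory` with columns
#'   `time`, `V1`, `V2`, `Iinput`, `motor_state`.
#' @export
integrate_circuit <- function(init, input, params,
                              dt_substep = NULL) {
  stopifnot(inherits(input, "input_series"))
  validate_circuit_params(params)
  if (is.null(dt_substep)) dt_substep <- min(input$dt, params$tau1 / 20)
  if (dt_substep > input$dt + 1e-12) stop("dt_substep must be <= input$dt")
  nsub <- max(1L, ceiling(input$dt / dt_substep - 1e-9))
  h <- input$dt / nsub
  n <- length(input$values)
  V1 <- numeric(n)
  V2 <- numeric(n)
  state <- as.numeric(init)
  if (length(state) != 2 || !all(is.finite(state))) {
    stop("init must be a finite numeric vector c(V1, V2)")
  }
  for (i in seq_len(n)) {
    I <- input$values[i]
    for (j in seq_len(nsub)) state <- rk4_step(state, I, params, h)
    if (!all(is.finite(state))) {
      stop("non-finite circuit state at input step ", i)
    }
    V1[i] <- state[1]
    V2[i] <- state[2]
  }
  motor <- motor_states_from_v2(V2, init_state = 1L)
  out <- data.frame(time = seq_len(n) * input$dt,
                    V1 = V1, V2 = V2, Iinput = input$values,
                    motor_state = motor)
  class(out) <- c("circuit_trajectory", "data.frame")
  out
}

## sign rule with tie -> previous state
motor_states_from_v2 <- function(V2, init_state = 1L) {
  m <- integer(length(V2))
  prev <- as.integer(init_state)
  for (i in seq_along(V2)) {
    if (V2[i] > 0) prev <- 1L else if (V2[i] < 0) prev <- 0L
    m[i] <- prev
  }
  m
}

## 1-D reduction used by the phase-plane tools: both nullclines are graphs,
##   V1-nullcline: V1 = (alpha*I + F12(V2) + C1)/gL1   (function of V2)
##   V2-nullcline: V2 = (F21(V1) + C2)/gL2             (function of V1)
## so intersections are roots of g(V1) = V1 - n1(n2(V1)).
v2_nullcline_of_v1 <- function(V1, params, ...) {
  (motor_drive(V1, params) + params$C2) / params$gL2
}

v1_nullcline_of_v2 <- function(V2, params, Iinput) {
  (params$alpha * Iinput + feedback_drive(V2, params) + params$C1) / params$gL1
}

nullcline_gap <- function(V1, params, Iinput) {
  V1 - v1_nullcline_of_v2(v2_nullcline_of_v1(V1, params), params, Iinput)
}

#' Nullclines and their intersections
#'
#' Samples both nullclines of the reduced circuit over a rectangular window
#' and counts their transversal intersections. Because each nullcline is the
#' graph of an explicit function (of `V2` and of `V1` respectively), the
#' intersections are bracketed by sign changes of a scalar gap function on a
#' `V1` grid and refined by bisection ([stats::uniroot()]).
#'
#' @param params a [circuit_params()] object.
#' @param Iinput constant input current (default 0).
#' @param grid numeric `c(lo, hi)` window applied to both axes
#'   (default `c(-2, 3)`, wide enough for all fixed points of the shipped
#'   presets).
#' @param n grid resolution per axis (default 201).
#' @return a list of class `phase_portrait`: data frames `v1_nullcline`
#'   (`V2`, `V1`) and `v2_nullcline` (`V1`, `V2`), `intersections`
#'   (`V1`, `V2`), and `n_intersections`.
#' @export
nullclines <- function(params, Iinput = 0, grid = c(-2, 3), n = 201) {
  validate_circuit_params(params)
  v1g <- seq(grid[1], grid[2], length.out = n)
  v2g <- seq(grid[1], grid[2], length.out = n)
  gap <- nullcline_gap(v1g, params, Iinput)
  roots <- refine_sign_changes(v1g, gap, function(x) {
    nullcline_gap(x, params, Iinput)
  })
  inter <- data.frame(V1 = roots,
                      V2 = v2_nullcline_of_v1(roots, params))
  out <- list(
    v1_nullcline = data.frame(V2 = v2g,
                              V1 = v1_nullcline_of_v2(v2g, params, Iinput)),
    v2_nullcline = data.frame(V1 = v1g,
                              V2 = v2_nullcline_of_v1(v1g, params)),
    intersections = inter,
    n_intersections = nrow(inter),
    grid = grid, Iinput = Iinput)
  class(out) <- "phase_portrait"
  out
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat(sprintf("<phase_portrait> %d nullcline intersection(s) on [%g, %g]^2\n",
              x$n_intersections, x$grid[1], x$grid[2]))
  if (x$n_intersections > 0) print(round(x$intersections, 4))
  invisible(x)
}

#' @param x a `phase_portrait`.
#' @param ... passed to [graphics::plot()].
#' @rdname nullclines
#' @export
plot.phase_portrait <- function(x, ...) {
  graphics::plot(x$v2_nullcline$V1, x$v2_nullcline$V2, type = "l",
                 col = "firebrick", xlab = "V1 (interneuron)",
                 ylab = "V2 (motor command)", ...)
  graphics::lines(x$v1_nullcline$V1, x$v1_nullcline$V2, col = "steelblue")
  if (x$n_intersections > 0) {
    graphics::points(x$intersections$V1, x$intersections$V2, pch = 19)
  }
  invisible(x)
}

## bracket sign changes on a grid and refine each by bisection; grid points
## that are exact roots are taken as-is (and only once)
refine_sign_changes <- function(xg, fg, f, tol = 1e-12) {
  roots <- xg[which(fg == 0)]
  idx <- which(fg[-length(fg)] * fg[-1] < 0)
  for (i in idx) {
    r <- tryCatch(
      stats::uniroot(f, c(xg[i], xg[i + 1]), tol = tol)$root,
      error = function(e) {
        stop("bisection refinement failed between grid points ",
             signif(xg[i], 6), " and ", signif(xg[i + 1], 6),
             "; use a finer grid")
      })
    roots <- c(roots, r)
  }
  sort(roots)
}

circuit_jacobian <- function(V1, V2, params) {
  matrix(c(-params$gL1 / params$tau1,
           motor_drive_deriv(V1, params) / params$tau2,
           feedback_drive_deriv(V2, params) / params$tau1,
           -params$gL2 / params$tau2),
         nrow = 2)
}

#' Fixed points of the reduced circuit and their stability
#'
#' Locates all fixed points inside the grid window (via the nullcline
#' intersection machinery), polishes each by damped 2-D Newton iteration with
#' the analytic Jacobian, merges duplicates, and classifies stability from
#' the Jacobian eigenvalues: `"stable"` if both real parts are negative,
#' `"saddle"` if they straddle zero, `"unstable"` otherwise.
#'
#' @inheritParams nullclines
#' @param newton_max maximum Newton iterations (default 50).
#' @param tol residual tolerance on the derivative norm (default 1e-10).
#' @param dedup_tol duplicate-merging tolerance (default 1e-6).
#' @return a `data.frame` with columns `V1`, `V2`, `eig1_re`, `eig1_im`,
#'   `eig2_re`, `eig2_im`, `stability`, `residual`, `refined`.
#' @export
find_fixed_points <- function(params, Iinput = 0, grid = c(-2, 3), n = 201,
                              newton_max = 50, tol = 1e-10, dedup_tol = 1e-6) {
  pp <- nullclines(params, Iinput, grid, n)
  pts <- pp$intersections
  out <- data.frame(V1 = numeric(0), V2 = numeric(0),
                    eig1_re = numeric(0), eig1_im = numeric(0),
                    eig2_re = numeric(0), eig2_im = numeric(0),
                    stability = character(0), residual = numeric(0),
                    refined = logical(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pts))) {
    st <- c(pts$V1[i], pts$V2[i])
    refined <- FALSE
    for (it in seq_len(newton_max)) {
      fv <- circuit_derivs(st, Iinput, params)
      if (sqrt(sum(fv^2)) < tol) {
        refined <- TRUE
        break
      }
      J <- circuit_jacobian(st[1], st[2], params)
      step <- tryCatch(solve(J, fv), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      st <- st - step
    }
    fv <- circuit_derivs(st, Iinput, params)
    res <- sqrt(sum(fv^2))
    if (!refined && res >= tol) {
      warning("Newton refinement did not converge for the fixed point near (",
              signif(pts$V1[i], 4), ", ", signif(pts$V2[i], 4), ")")
    } else {
      refined <- TRUE
    }
    ev <- eigen(circuit_jacobian(st[1], st[2], params),
                only.values = TRUE)$values
    ev <- ev[order(Re(ev), decreasing = TRUE)]
    re <- Re(ev)
    stab <- if (all(re < 0)) "stable"
            else if (any(re < 0) && any(re > 0)) "saddle"
            else "unstable"
    out[nrow(out) + 1L, ] <- list(st[1], st[2], Re(ev[1]), Im(ev[1]),
                                  Re(ev[2]), Im(ev[2]), stab, res, refined)
  }
  ## merge duplicates within tolerance
  if (nrow(out) > 1) {
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out) - 1)) {
      if (!keep[i]) next
      for (j in seq(i + 1, nrow(out))) {
        if (keep[j] &&
            max(abs(out$V1[i] - out$V1[j]), abs(out$V2[i] - out$V2[j])) <
              dedup_tol) {
          keep[j] <- FALSE
        }
      }
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Autocorrelative persistence timescale of a sampled signal
#'
#' Returns the first lag at which the normalized autocorrelation (mean
#' subtracted, unbiased lag normalization) falls below `1/e`, with linear
#' interpolation between lags. If the autocorrelation never crosses `1/e`
#' within half the series length the timescale is reported as `Inf`; a
#' constant series also returns `Inf`, with a warning.
#'
#' @param x numeric series (length >= 10).
#' @param dt sampling interval.
#' @return the timescale in units of `dt` (possibly `Inf`).
#' @export
autocorr_timescale <- function(x, dt) {
  if (length(x) < 10) stop("series must have at least 10 samples")
  if (!all(is.finite(x))) stop("non-finite values in series")
  x <- x - mean(x)
  r0 <- mean(x^2)
  if (r0 == 0) {
    warning("constant series: autocorrelation timescale undefined, ",
            "returning Inf")
    return(Inf)
  }
  n <- length(x)
  target <- exp(-1)
  prev <- 1
  for (L in seq_len(floor(n / 2))) {
    r <- sum(x[seq_len(n - L)] * x[seq(L + 1, n)]) / (n - L) / r0
    if (r < target) {
      return(dt * (L - 1 + (prev - target) / (prev - r)))
    }
    prev <- r
  }
  Inf
}
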