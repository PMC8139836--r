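test_that("feedback drive follows the logistic form and its bounds", {
  p <- circuit_params(wfb = 1)
  expect_equal(feedback_drive(0, circuit_params(wfb = 0)), 0)
  expect_equal(feedback_drive(50, p), 1, tolerance = 1e-12)
  expect_equal(feedback_drive(0, p), 0.5)  # k1 = 15, beta1 = 0 midpoint
  v2 <- seq(-5, 5, length.out = 201)
  for (wfb in c(-1, 0.5, 1)) {
    pw <- circuit_params(wfb = wfb)
    expect_true(all(abs(feedback_drive(v2, pw)) <= abs(wfb) + 1e-12))
  }
  expect_error(feedback_drive(NaN, p), "non-finite")
})

test_that("motor drive: odd-symmetric form switches sign, literal form is
           degenerate", {
  p <- circuit_params(wfb = 1)  # calibrated: beta2 = beta2p = 1.0
  ## odd symmetry about the inflection point
  expect_equal(motor_drive(p$beta2, p), 0)
  expect_equal(motor_drive(p$beta2 + 0.3, p),
               -motor_drive(p$beta2 - 0.3, p), tolerance = 1e-12)
  ## closed form: equal heights/steepness collapse to a tanh switch
  expect_equal(motor_drive(0.5, p), tanh(2.5 * (0.5 - 1.0)))
  expect_equal(motor_drive(0.5, p), -0.84828364, tolerance = 1e-7)
  ## the same value from direct evaluation of the two sigmoids
  sig <- function(z) 1 / (1 + exp(-z))
  expect_equal(motor_drive(0.5, p),
               sig(5 * (0.5 - 1)) - sig(-5 * (0.5 - 1)), tolerance = 1e-12)
  ## printed literal form with symmetric pool parameters cancels everywhere
  plit <- circuit_params(wfb = 1, form = "literal")
  expect_equal(motor_drive(seq(-2, 3, by = 0.1), plit),
               rep(0, 51), tolerance = 1e-12)
  ## bound by w21 * max(gamma1, gamma2)
  v1 <- seq(-5, 5, length.out = 201)
  expect_true(all(abs(motor_drive(v1, p)) <=
                    p$w21 * max(p$gamma1, p$gamma2) + 1e-12))
})

test_that("AFD steady state matches the relaxed full model", {
  full <- full_model_params(tau0 = 1.3, gL0 = 2, VL0 = 0.4, R = 1.5)
  expect_equal(afd_steady_state(0, full), full$VL0)
  ## linearity: doubling the input doubles the deviation from rest
  d1 <- afd_steady_state(0.3, full) - full$VL0
  d2 <- afd_steady_state(0.6, full) - full$VL0
  expect_equal(d2, 2 * d1)
  ## independent oracle: relax the AFD ODE to convergence
  skip_if_not_installed("deSolve")
  for (I in c(-0.5, 0.2, 1)) {
    sol <- deSolve::lsoda(
      y = c(V0 = 0), times = c(0, 60),
      func = function(t, y, parms) {
        list((-full$gL0 * (y - full$VL0) + I * full$R) / full$tau0)
      }, parms = NULL, rtol = 1e-10, atol = 1e-10)
    expect_equal(unname(sol[2, "V0"]), afd_steady_state(I, full),
                 tolerance = 1e-7)
  }
})

test_that("derivatives vanish at fixed points and scale with tau", {
  p <- circuit_params(wfb = 1)
  fp <- find_fixed_points(p)
  for (i in seq_len(nrow(fp))) {
    d <- circuit_derivs(c(fp$V1[i], fp$V2[i]), 0, p)
    expect_lt(sqrt(sum(d^2)), 1e-8)
  }
  ## closed-form interneuron equilibrium without feedback
  p0 <- circuit_params(wfb = 0)
  expect_equal(circuit_derivs(c(p0$C1 / p0$gL1, 0.3), 0, p0)[1], 0)
  ## halving tau1 doubles dV1/dt
  p_half <- circuit_params(wfb = 1, tau1 = p$tau1 / 2)
  st <- c(0.2, -0.4)
  expect_equal(circuit_derivs(st, 0.1, p_half)[1],
               2 * circuit_derivs(st, 0.1, p)[1])
})

test_that("RK4 integration holds equilibria and converges to fixed points", {
  p <- circuit_params(wfb = 1)
  fp <- find_fixed_points(p)
  stable <- fp[fp$stability == "stable", ]
  const_input <- input_series(rep(0, 50), dt = 1)
  ## stays at a stable fixed point
  tr <- integrate_circuit(c(stable$V1[1], stable$V2[1]), const_input, p)
  expect_lt(max(abs(tr$V1 - stable$V1[1])), 1e-8)
  expect_lt(max(abs(tr$V2 - stable$V2[1])), 1e-8)
  ## the published initial state integrates without error
  expect_no_error(integrate_circuit(c(1, 1), const_input, p))
  ## any start relaxes onto one of the located fixed points
  set.seed(7)
  for (i in 1:5) {
    init <- stats::runif(2, -1.5, 2.5)
    tr <- integrate_circuit(init, input_series(rep(0, 80), dt = 1), p)
    endpt <- c(tr$V1[nrow(tr)], tr$V2[nrow(tr)])
    dists <- sqrt((fp$V1 - endpt[1])^2 + (fp$V2 - endpt[2])^2)
    expect_lt(min(dists), 1e-5)
  }
})

test_that("RK4 trajectories agree under step halving", {
  set.seed(11)
  p <- circuit_params(wfb = 1)
  input <- oscillating_input(duration = 400, noise_sd = 0.15)
  tr1 <- integrate_circuit(c(1, 1), input, p, dt_substep = p$tau1 / 20)
  tr2 <- integrate_circuit(c(1, 1), input, p, dt_substep = p$tau1 / 40)
  expect_lt(max(abs(tr1$V1 - tr2$V1), abs(tr1$V2 - tr2$V2)), 1e-5)
})

test_that("motor-state labels follow the sign rule with sticky ties", {
  v2 <- c(0.5, -0.2, 0, 0, 0.1, 0)
  expect_identical(motor_state_of(v2), c(1L, 0L, 0L, 0L, 1L, 1L))
  expect_identical(motor_state_of(0, previous = 0L), 0L)
})

test_that("nullcline intersection counts match a dense brute-force count", {
  for (cfg in list(list(wfb = 1, I = 0, n_expected = 3),
                   list(wfb = 0, I = 0, n_expected = 1),
                   list(wfb = -1, I = 0, n_expected = 1),
                   list(wfb = 1, I = 0.2, n_expected = NA),
                   list(wfb = 1, I = -0.5, n_expected = NA))) {
    p <- circuit_params(wfb = cfg$wfb)
    pp <- nullclines(p, Iinput = cfg$I)
    expect_equal(pp$n_intersections,
                 count_intersections_dense(p, cfg$I))
    if (!is.na(cfg$n_expected)) {
      expect_equal(pp$n_intersections, cfg$n_expected)
    }
  }
})

test_that("fixed points: bistability with positive feedback, closed form
           without", {
  p <- circuit_params(wfb = 1)
  fp <- find_fixed_points(p)
  expect_equal(nrow(fp), 3)
  expect_equal(sum(fp$stability == "stable"), 2)
  ## middle intersection is the saddle between the two states
  mid <- fp[order(fp$V1)[2], ]
  expect_equal(mid$stability, "saddle")
  expect_true(mid$eig1_re > 0 && mid$eig2_re < 0)
  ## every residual is tiny and the count matches the nullcline portrait
  expect_true(all(fp$residual < 1e-8))
  expect_equal(nrow(fp), nullclines(p)$n_intersections)
  ## no feedback: single fixed point at the closed-form location
  p0 <- circuit_params(wfb = 0)
  fp0 <- find_fixed_points(p0)
  expect_equal(nrow(fp0), 1)
  expect_equal(fp0$stability, "stable")
  expect_equal(fp0$V1, p0$C1 / p0$gL1, tolerance = 1e-9)
  expect_equal(fp0$V2, tanh(p0$k2 / 2 * (p0$C1 / p0$gL1 - p0$beta2)),
               tolerance = 1e-9)
  ## negative feedback also monostable
  expect_equal(sum(find_fixed_points(
    circuit_params(wfb = -1))$stability == "stable"), 1)
})

test_that("stability labels agree with a finite-difference Jacobian", {
  p <- circuit_params(wfb = 1)
  fp <- find_fixed_points(p)
  h <- 1e-6
  for (i in seq_len(nrow(fp))) {
    st <- c(fp$V1[i], fp$V2[i])
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      e <- c(0, 0)
      e[j] <- h
      J[, j] <- (circuit_derivs(st + e, 0, p) -
                   circuit_derivs(st - e, 0, p)) / (2 * h)
    }
    re <- Re(eigen(J, only.values = TRUE)$values)
    lbl <- if (all(re < 0)) "stable" else if (any(re < 0) && any(re > 0)) {
      "saddle"
    } else {
      "unstable"
    }
    expect_equal(fp$stability[i], lbl)
  }
})

test_that("autocorrelation timescale has its closed-form cosine value", {
  P <- 40
  dt <- 0.05
  x <- cos(2 * pi * seq(0, 50 * P, by = dt) / P)
  expect_equal(autocorr_timescale(x, dt), P / (2 * pi) * acos(exp(-1)),
               tolerance = 0.02)
  ## white noise decorrelates within a lag or two
  set.seed(5)
  expect_lte(autocorr_timescale(rnorm(5000), dt = 1), 2)
  ## constant series: timescale undefined, reported as Inf
  expect_warning(ts_const <- autocorr_timescale(rep(2, 100), 1), "constant")
  expect_identical(ts_const, Inf)
  expect_error(autocorr_timescale(1:5, 1), "at least 10")
})

test_that("positive feedback sustains states beyond the stimulus period", {
  set.seed(3)
  input <- oscillating_input(duration = 2000)
  period <- 40
  p_pos <- circuit_params(wfb = 1)
  p_no <- circuit_params(wfb = 0)
  v2_pos <- integrate_circuit(c(1, 1), input, p_pos)$V2
  v2_no <- integrate_circuit(c(1, 1), input, p_no)$V2
  expect_gt(autocorr_timescale(v2_pos, input$dt), period)
  expect_lt(autocorr_timescale(v2_no, input$dt), period)
})
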