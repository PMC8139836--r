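test_that("thermotactic bias: projections, sign conventions, exclusions", {
  expect_equal(thermotactic_bias(straight_track(20, 0))$mean, 1)
  expect_equal(thermotactic_bias(straight_track(20, 90))$mean, 0,
               tolerance = 1e-12)
  expect_equal(thermotactic_bias(straight_track(20, 180))$mean, -1)
  ## the assay convention: warm along -x gives the classical -vx/|v|
  tk <- as_track(1:20, -(1:20), rep(0, 20), warm_axis = c(-1, 0))
  expect_equal(thermotactic_bias(tk)$mean, 1)
  ## crafted three-segment zigzag against the hand-computed average
  tk <- heading_track(c(0, 0, 60, 180))
  expect_equal(thermotactic_bias(tk)$mean,
               mean(c(cos(0), cos(pi / 3), cos(pi))))
  ## bias is bounded and negates under time reversal
  set.seed(8)
  tk <- heading_track(runif(60, -180, 180))
  b <- thermotactic_bias(tk)
  expect_true(all(abs(b$per_frame) <= 1 + 1e-12, na.rm = TRUE))
  rev_tk <- as_track(tk$time, rev(tk$x), rev(tk$y))
  expect_equal(thermotactic_bias(rev_tk)$mean, -b$mean, tolerance = 1e-12)
  ## all-stationary tracks are rejected
  expect_error(thermotactic_bias(as_track(1:5, rep(0, 5), rep(0, 5))),
               "no moving frames")
})

test_that("run segmentation partitions the labeled track", {
  tk <- straight_track(6, motor_state = c(1, 1, 1, 0, 0, 1))
  seg <- segment_runs(tk)
  expect_equal(seg$state, c(1, 0, 1))
  expect_equal(seg$i_start, c(1L, 4L, 6L))
  expect_equal(seg$i_end, c(3L, 5L, 6L))
  expect_equal(sum(seg$duration), 6)
  ## single run spanning the whole track
  seg1 <- segment_runs(straight_track(10, motor_state = rep(1, 10)))
  expect_equal(nrow(seg1), 1)
  expect_equal(seg1$duration, 10)
  ## alternation at every frame: one epoch per frame, total preserved
  segalt <- segment_runs(straight_track(8, motor_state = rep(c(1, 0), 4)))
  expect_equal(nrow(segalt), 8)
  expect_equal(sum(segalt$duration), 8)
  expect_error(segment_runs(straight_track(1, motor_state = 1)), "shorter")
})

test_that("velocity fallback labels reversals as motion against the
           heading proxy", {
  ## forward 20 frames, backtrack 6, forward again
  headings <- c(rep(0, 20), rep(180, 6), rep(0, 14))
  tk <- heading_track(headings, dt = 0.25)
  seg <- segment_runs(tk)
  expect_gte(nrow(seg), 3)
  expect_equal(seg$state[1], 1)
  expect_true(any(seg$state == 0))
})

test_that("run durations bin by overall direction", {
  runs <- data.frame(state = 1, i_start = 1L, i_end = 2L, t_start = 0,
                     t_end = 1, duration = c(2, 4), direction_deg = c(0, 5))
  out <- run_duration_by_direction(runs)
  expect_equal(nrow(out), 1)
  expect_equal(out$mean_duration, 3)
  expect_equal(out$bin_center_deg, 0)
  expect_equal(out$n, 2L)
  expect_equal(out$sem, sd(c(2, 4)) / sqrt(2))
  ## one giant bin reproduces the grand mean
  runs$direction_deg <- c(10, -170)
  expect_equal(run_duration_by_direction(runs, bin_width = 360)$mean_duration,
               3)
  ## zero-displacement runs are skipped with a warning
  runs$direction_deg <- c(0, NA)
  expect_warning(out <- run_duration_by_direction(runs), "zero-displacement")
  expect_equal(out$n, 1L)
})

test_that("synthetic wild-type tracks show longer runs up the gradient", {
  cfg <- synth_config(seed = 14, duration = 2000, mode = "wildtype")
  tks <- make_tracks(cfg, n = 12)
  runs <- do.call(rbind, lapply(tks$tracks, segment_runs))
  out <- suppressWarnings(run_duration_by_direction(runs, bin_width = 90))
  up <- out$mean_duration[out$bin_center_deg == 0]
  down <- out$mean_duration[out$bin_center_deg == -180]
  expect_gt(up, down)
})

test_that("temperature-change series and up-gradient histogram", {
  tk <- straight_track(20, 0, speed = 2, dt = 0.5)
  dd <- dtdt_series(tk, cT = 0.1)
  expect_equal(dd$dtdt, rep(0.1 * 2, 19))
  expect_equal(dtdt_series(tk, cT = 0)$dtdt, rep(0, 19))
  ## a zigzag spending 30% of frames heading down shows 30% negative mass
  headings <- rep(c(0, 0, 0, 0, 0, 0, 0, 180, 180, 180), 10)
  tk <- heading_track(headings, motor_state = rep(1, 100))
  runs <- segment_runs(tk)
  ## net displacement is up-gradient, so the single run qualifies
  dd <- dtdt_series(tk, cT = 0.1, runs = runs)
  expect_equal(mean(dd$up_run_values < 0), 0.3, tolerance = 0.02)
})

test_that("cooling epochs: square wave recovered exactly, blips dropped", {
  expect_equal(nrow(detect_cooling_epochs(rep(0.2, 50), 1)), 0)
  square <- rep(c(rep(0.1, 10), rep(-0.1, 10)), 3)
  ep <- detect_cooling_epochs(square, frame_dt = 1, min_duration = 5)
  expect_equal(nrow(ep), 3)
  expect_equal(ep$i_start, c(11L, 31L, 51L))
  expect_equal(ep$i_end, c(20L, 40L, 60L))
  expect_true(all(ep$mean_dtdt < 0))
  ## epochs are disjoint
  expect_true(all(ep$i_start[-1] > ep$i_end[-nrow(ep)]))
  ## a negative blip shorter than min_duration is excluded
  blip <- c(rep(0.1, 20), rep(-0.1, 3), rep(0.1, 20))
  expect_equal(nrow(detect_cooling_epochs(blip, 1, min_duration = 5)), 0)
})

test_that("post-cooling reversal fraction: extremes and time-rescaling
           invariance", {
  square <- rep(c(rep(0.1, 10), rep(-0.1, 10)), 4)
  cool <- detect_cooling_epochs(square, 1, min_duration = 5)
  ## all-forward labels: no reversals anywhere
  out <- post_cooling_reversal_fraction(cool, rep(1, 80), 1,
                                        duration_bins = c(5, 15))
  expect_equal(out$fraction, 0)
  ## reversal right after every cooling offset
  states <- rep(1, 80)
  states[cool$i_end + 1] <- 0
  out <- post_cooling_reversal_fraction(cool, states, 1,
                                        duration_bins = c(5, 15))
  expect_equal(out$fraction, 1)
  expect_true(out$ci_lo <= 1 && out$ci_hi >= 1)
  ## empty bins are NA, not zero
  expect_true(is.na(post_cooling_reversal_fraction(
    cool, states, 1, duration_bins = c(100, 200))$fraction))
  ## uniform time rescaling of inputs and windows leaves fractions unchanged
  cool2 <- detect_cooling_epochs(square, 0.5, min_duration = 2.5)
  out2 <- post_cooling_reversal_fraction(cool2, states, 0.5,
                                         response_window = 1,
                                         duration_bins = c(2.5, 7.5))
  expect_equal(out2$fraction, 1)
})

test_that("fraction of runs ending after cooling", {
  runs <- data.frame(state = c(1, 0, 1), i_start = c(1L, 21L, 26L),
                     i_end = c(20L, 25L, 50L), t_start = c(1, 21, 26),
                     t_end = c(20, 25, 50), duration = c(20, 5, 25),
                     direction_deg = 0)
  none <- detect_cooling_epochs(rep(0.1, 50), 1)
  expect_equal(run_end_after_cooling_fraction(runs, none), 0)
  ## cooling ending exactly at the first run's end
  dtdt <- rep(0.1, 50)
  dtdt[15:20] <- -0.1
  cool <- detect_cooling_epochs(dtdt, 1, min_duration = 3)
  expect_equal(run_end_after_cooling_fraction(runs, cool), 0.5)
  expect_error(run_end_after_cooling_fraction(runs[runs$state == 0, ], cool),
               "no forward runs")
})
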