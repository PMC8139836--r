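# shared fixtures built in code

# straight-line track at constant speed, heading in degrees from the warm
# (+x) axis
straight_track <- function(n = 50, heading_deg = 0, speed = 1, dt = 1,
                           motor_state = NULL) {
  th <- heading_deg * pi / 180
  tt <- seq_len(n) * dt
  as_track(tt, speed * dt * cumsum(rep(cos(th), n)),
           speed * dt * cumsum(rep(sin(th), n)), motor_state)
}

# track built from a per-frame heading sequence (degrees)
heading_track <- function(headings_deg, speed = 1, dt = 1,
                          motor_state = NULL) {
  th <- headings_deg * pi / 180
  as_track(seq_along(th) * dt, cumsum(speed * dt * cos(th)),
           cumsum(speed * dt * sin(th)), motor_state)
}

# brute-force between-class variance maximizer over histogram cut points,
# written independently of the package's cumulative-sum implementation
otsu_bruteforce <- function(x, n_bins = 256) {
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(x, edges,
                                            rightmost.closed = TRUE), 1L),
                          n_bins), nbins = n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  best_bcv <- -Inf
  best_k <- NA_integer_
  for (k in seq_len(n_bins - 1)) {
    n0 <- sum(counts[1:k])
    n1 <- sum(counts[(k + 1):n_bins])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / n1
    w0 <- n0 / (n0 + n1)
    bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (bcv > best_bcv + 1e-15) {
      best_bcv <- bcv
      best_k <- k
    }
  }
  list(threshold = edges[best_k + 1], between_var = best_bcv)
}

# dense-grid count of nullcline intersections, independent of the
# bracketing/bisection path
count_intersections_dense <- function(params, Iinput = 0, lims = c(-2, 3),
                                      n = 200001) {
  v1 <- seq(lims[1], lims[2], length.out = n)
  v2_on_motor_nullcline <- (motor_drive(v1, params) + params$C2) / params$gL2
  v1_back <- (params$alpha * Iinput +
                feedback_drive(v2_on_motor_nullcline, params) + params$C1) /
    params$gL1
  ## transversal crossings flip the sign once; exact zeros on the grid are
  ## stripped so they are not double counted
  s <- sign(v1 - v1_back)
  s <- s[s != 0]
  sum(diff(s) != 0)
}
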