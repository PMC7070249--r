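# shared simulated fixtures, built once per test run
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, expr) {
  if (!exists(key, envir = .sim_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

healthy_trial_8 <- function() {
  cached_sim("h8", simulate_trial(n_strides = 8, seed = 9))
}

healthy_analysis_8 <- function() {
  cached_sim("a8", analyze_trace(healthy_trial_8()$traces$left))
}

# a perfectly stationary trace (foot flat on the ground, no noise)
stationary_trace <- function(n = 400, fs = 100) {
  t <- (seq_len(n) - 1) / fs
  imu_trace(t, matrix(rep(c(0, 0, 9.81), each = n), n, 3),
            matrix(0, n, 3))
}

# independent fine-step attitude oracle: piecewise-constant exact rotations
# exp(0.5 * w_mid * h) at substep resolution, linearly interpolating omega
oracle_attitude <- function(q0, w_fun, t_end, h) {
  q <- q0
  n <- round(t_end / h)
  for (k in seq_len(n)) {
    t0 <- (k - 1) * h
    wm <- w_fun(t0 + h / 2)
    ang <- sqrt(sum(wm^2)) * h
    dq <- if (ang == 0) c(1, 0, 0, 0) else {
      c(cos(ang / 2), sin(ang / 2) * wm / sqrt(sum(wm^2)))
    }
    q <- quat_normalize(quat_multiply(q, dq))
  }
  q
}

quat_angle_between <- function(a, b) {
  d <- quat_multiply(quat_conjugate(a), b)
  2 * acos(pmin(1, abs(d[1])))
}

# exhaustive minimum within-cluster-SS bipartition of a numeric vector
brute_force_2partition <- function(d) {
  n <- length(d)
  best <- NULL
  for (m in seq_len(2^n - 2)) {
    sel <- as.logical(bitwAnd(m, 2^(seq_len(n) - 1)))
    a <- d[sel]; b <- d[!sel]
    wss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (is.null(best) || wss < best$wss - 1e-15) {
      best <- list(wss = wss, sel = sel)
    }
  }
  # orient so TRUE marks the cluster with the larger mean
  if (mean(d[best$sel]) < mean(d[!best$sel])) best$sel <- !best$sel
  best
}
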