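test_that("quaternion algebra follows the Hamilton convention", {
  q <- quat_normalize(c(0.9, 0.2, -0.3, 0.1))
  expect_equal(quat_multiply(quat_identity(), q), q)
  expect_equal(quat_multiply(q, quat_conjugate(q)), quat_identity(),
               tolerance = 1e-12)
  # two quarter turns about z compose to a half turn
  q90 <- quat_from_axis_angle(c(0, 0, 1), pi / 2)
  expect_equal(quat_multiply(q90, q90), c(0, 0, 0, 1), tolerance = 1e-12)
  # unit x unit stays unit
  set.seed(1)
  for (i in 1:20) {
    a <- quat_normalize(rnorm(4))
    b <- quat_normalize(rnorm(4))
    expect_equal(sum(quat_multiply(a, b)^2), 1, tolerance = 1e-12)
  }
})

test_that("RK4 attitude step matches the constant-rate closed form", {
  w <- c(0, 0, pi / 2)
  q <- quat_identity()
  for (k in 1:100) q <- rk4_attitude_step(q, w, w, 0.01)
  expect_equal(q, c(cos(pi / 4), 0, 0, sin(pi / 4)), tolerance = 1e-6)
  # zero rate leaves the attitude unchanged
  q0 <- quat_normalize(c(1, 0.1, 0.2, 0.05))
  expect_equal(rk4_attitude_step(q0, c(0, 0, 0), c(0, 0, 0), 0.01), q0,
               tolerance = 1e-15)
  expect_error(rk4_attitude_step(q0, w, w, 0), "dt")
})

test_that("RK4 tracks a smooth time-varying rate against a fine-step oracle", {
  dt <- 0.01
  ts <- seq(0, 1, by = dt)
  w_samp <- cbind(0.8 * sin(2 * pi * ts), 1.5 * cos(3 * ts),
                  0.5 * sin(5 * ts + 1))
  q <- quat_identity()
  for (k in seq_len(length(ts) - 1)) {
    q <- rk4_attitude_step(q, w_samp[k, ], w_samp[k + 1, ], dt)
  }
  # the oracle integrates the same piecewise-linear rate signal implied by
  # the samples, by exact exponential substeps at dt/100
  w_interp <- function(t) {
    vapply(1:3, function(j) stats::approx(ts, w_samp[, j], t,
                                          rule = 2)$y, numeric(1))
  }
  q_ref <- oracle_attitude(quat_identity(), w_interp, 1, dt / 100)
  expect_lt(quat_angle_between(q, q_ref), 1e-6)
})

test_that("rotate_to_nav agrees with the rotation-matrix oracle", {
  expect_equal(rotate_to_nav(quat_identity(), c(0, 0, 9.81)), c(0, 0, 9.81))
  qx <- quat_from_axis_angle(c(1, 0, 0), pi / 2)
  expect_equal(rotate_to_nav(qx, c(0, 0, 1)), c(0, -1, 0), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:20) {
    q <- quat_normalize(rnorm(4))
    v <- rnorm(3)
    expect_equal(rotate_to_nav(q, v), as.numeric(quat_to_matrix(q) %*% v),
                 tolerance = 1e-12)
    # isometry and conjugate inversion
    expect_equal(sqrt(sum(rotate_to_nav(q, v)^2)), sqrt(sum(v^2)),
                 tolerance = 1e-12)
    expect_equal(rotate_to_nav(quat_conjugate(q), rotate_to_nav(q, v)), v,
                 tolerance = 1e-12)
  }
})

test_that("quaternion norm stays unit over 1e5 renormalized RK4 steps", {
  w_fun <- function(t) c(2 * sin(t), 1.3 * cos(2 * t), 0.7)
  q <- quat_identity()
  dt <- 0.001
  for (k in seq_len(1e5)) {
    q <- rk4_attitude_step(q, w_fun((k - 1) * dt), w_fun(k * dt), dt)
  }
  expect_lt(abs(sqrt(sum(q^2)) - 1), 1e-12)
})

test_that("strapdown integration holds still on a stationary trace", {
  tr <- stationary_trace()
  nav <- strapdown_integrate(tr, q0 = quat_identity())
  expect_lt(max(abs(as.matrix(nav[, c("vx", "vy", "vz")]))), 1e-12)
  expect_lt(max(abs(as.matrix(nav[, c("px", "py", "pz")]))), 1e-12)
})

test_that("a constant accelerometer bias integrates to linear velocity drift", {
  n <- 500
  t <- (seq_len(n) - 1) / 100
  tr <- imu_trace(t, matrix(c(0.1, 0, 9.81), n, 3, byrow = TRUE),
                  matrix(0, n, 3))
  nav <- strapdown_integrate(tr, q0 = quat_identity())
  expect_equal(nav$vx, 0.1 * t, tolerance = 1e-9)
  expect_lt(max(abs(nav$vz)), 1e-12)
})

test_that("forward integration of inverse-strapdown output reproduces truth", {
  tr <- simulate_trial(n_strides = 1, noise = FALSE, fs = 1000,
                       lead_s = 0.5, tail_s = 0.3)
  tl <- tr$traces$left
  th <- tr$truth$left
  nav <- strapdown_integrate(tl, q0 = th$quat[1, ], gyro_bias = c(0, 0, 0))
  p <- as.matrix(nav[, c("px", "py", "pz")])
  p_true <- sweep(th$pos, 2, th$pos[1, ])
  expect_lt(max(abs(p - p_true)), 1e-4)
})
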