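test_that("detect_stance marks a stationary trace as all stance", {
  tr <- stationary_trace()
  m <- detect_stance(tr)
  expect_true(all(m$mask))
  expect_error(detect_stance(tr, Wd = 1000), "larger than the trace")
})

test_that("detection is monotone in the threshold Td", {
  tr <- healthy_trial_8()$traces$left
  m_lo <- detect_stance(tr, Td = 0.01)
  m_mid <- detect_stance(tr, Td = 3)
  m_hi <- detect_stance(tr, Td = 1e9)
  expect_true(all(m_hi$mask))
  expect_lt(sum(m_lo$mask), sum(m_mid$mask))
  # a sample flagged at a low threshold stays flagged at a higher one
  expect_true(all(m_mid$mask[m_lo$mask]))
})

test_that("cycle bias follows the end-of-swing velocity law", {
  b <- estimate_cycle_bias(c(0.06, 0, 0.03), 0.6)
  expect_equal(b$epsilon, c(0.1, 0, 0.05))
  expect_equal(estimate_cycle_bias(c(0, 0, 0), 0.5)$epsilon, c(0, 0, 0))
  expect_error(estimate_cycle_bias(c(1, 0, 0), 0), "positive")
  # zero bias leaves the swing velocity untouched
  v <- cbind(seq(0, 1, length.out = 11), 0, 0)
  expect_equal(correct_velocity(v, seq(0, 1, 0.1), c(0, 0, 0)), v)
  # linear de-drift forces zero at swing end
  vc <- correct_velocity(v, seq(0, 1, 0.1),
                         estimate_cycle_bias(v[11, ], 1))
  expect_equal(vc[11, ], c(0, 0, 0), tolerance = 1e-15)
})

test_that("corrected velocity is exactly zero through every stance", {
  a <- healthy_analysis_8()
  v <- as.matrix(a$zupt$nav[, c("vx", "vy", "vz")])
  expect_lt(max(abs(v[a$zupt$mask$mask, ])), 1e-9)
  # and returns to zero at each swing end by construction
  iv <- a$zupt$intervals
  expect_lt(max(abs(v[iv$start, ])), 1e-9)
})

test_that("an injected constant accelerometer bias is recovered per cycle", {
  # fine sampling so the end-of-swing velocity reflects the bias alone,
  # not the integrator's discretization residue
  tr <- simulate_trial(n_strides = 4, noise = FALSE, lead_s = 1, tail_s = 1,
                       fs = 1000)
  tl <- tr$traces$left
  th <- tr$truth$left
  b <- c(0.05, 0, 0.03)
  tr_b <- imu_trace(tl$t, sweep(tl$accel, 2, -b), tl$gyro)
  cal <- structure(list(q0 = th$quat[1, ], gyro_bias = c(0, 0, 0),
                        g_ref = 9.81, quiescent = TRUE, window = c(1, 100)),
                   class = "imu_calibration")
  z <- zupt_correct(tr_b, calibration = cal)
  # the recovered epsilon of each cycle should equal the time-mean of the
  # body-frame bias rotated into the navigation frame over that cycle
  iv <- z$intervals
  for (j in seq_len(nrow(iv) - 1)) {
    idx <- (iv$end[j] - 1):iv$start[j + 1]
    expected <- colMeans(t(vapply(idx, function(i)
      rotate_to_nav(th$quat[i, ], b), numeric(3))))
    expect_lt(max(abs(z$bias[[j]]$epsilon - expected)), 2e-3)
  }
})

test_that("position reconstruction integrates corrected velocity", {
  p <- reconstruct_position(matrix(0, 50, 3), 0.01, c(1, 2, 3))
  expect_equal(p, matrix(rep(c(1, 2, 3), each = 50), 50, 3))
  # one noise-free stride: displacement matches ground truth closely
  tr <- simulate_trial(n_strides = 1, noise = FALSE, lead_s = 1, tail_s = 1)
  z <- zupt_correct(tr$traces$left)
  p <- as.matrix(z$nav[, c("px", "py", "pz")])
  p_true <- sweep(tr$truth$left$pos, 2, tr$truth$left$pos[1, ])
  expect_lt(max(abs(p[nrow(p), ] - p_true[nrow(p_true), ])), 1e-3)
})

test_that("drift does not accumulate across strides after correction", {
  tr <- healthy_trial_8()
  tl <- tr$traces$left
  th <- tr$truth$left
  z <- zupt_correct(tl)
  p_true <- sweep(th$pos, 2, th$pos[1, ])
  err_corr <- as.matrix(z$nav[, c("px", "py", "pz")]) - p_true
  err_raw <- as.matrix(z$raw[, c("px", "py", "pz")]) - p_true
  n <- nrow(err_corr)
  expect_lt(sqrt(sum(err_corr[n, ]^2)), 0.1 * sqrt(sum(err_raw[n, ]^2)))
  expect_lt(max(abs(err_corr[, 1])), 0.05)
})
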