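test_that("generated events realize the template partition exactly", {
  tpl <- gait_template("healthy")
  th <- generate_trajectory(tpl, n_strides = 5)
  st <- tpl$stride_time
  expect_equal((th$events$toeoff_t - th$events$touchdown_t[1:5]) / st,
               rep(tpl$stance_fraction, 5))
  # total displacement is exactly n strides
  expect_equal(max(th$pos[, 1]) - th$pos[1, 1],
               5 * tpl$stride_length)
  expect_error(generate_trajectory(tpl, 1, fs = 5), "infeasible")
})

test_that("the foot trajectory is C1: no velocity jumps at phase edges", {
  # stride time 1 s puts every phase boundary exactly on a sample
  tpl <- gait_template(stride_time = 1, stance_fraction = 0.62)
  th <- generate_trajectory(tpl, n_strides = 3, lead_s = 1, tail_s = 1)
  idx_td <- th$events$touchdown_idx
  expect_lt(max(abs(th$vel[idx_td, ])), 1e-9)
  idx_to <- round(th$events$toeoff_t * th$fs) + 1L
  expect_lt(max(abs(th$vel[idx_to, ])), 1e-9)
  # between samples the velocity moves by at most a_max * dt
  a_max <- max(sqrt(rowSums(th$acc^2)))
  expect_lt(max(abs(diff(th$pos[, 1]) * th$fs - th$vel[-1, 1])),
            a_max / th$fs)
})

test_that("ground truth is internally consistent", {
  tpl <- gait_template("healthy")
  th <- generate_trajectory(tpl, n_strides = 6)
  m <- th$metrics
  expect_equal(m$stride_length_m, tpl$stride_length, tolerance = 1e-12)
  expect_equal(m$walking_speed_mps, tpl$stride_length / tpl$stride_time,
               tolerance = 1e-12)
  expect_equal(m$cadence_spm, 120 / tpl$stride_time, tolerance = 1e-12)
  expect_equal(m$stance_ratio, tpl$stance_fraction)
  expect_equal(m$max_foot_elevation_m, tpl$foot_clearance, tolerance = 1e-3)
  expect_equal(m$ankle_rom_deg, tpl$ankle_rom, tolerance = 0.1)
  # stored elevation equals a fresh measurement off the stored trajectory
  ev <- vapply(1:6, function(i) {
    idx <- th$t >= th$events$touchdown_t[i] &
      th$t < th$events$touchdown_t[i + 1]
    max(th$pos[idx, 3])
  }, numeric(1))
  expect_equal(mean(ev), m$max_foot_elevation_m, tolerance = 1e-12)
})

test_that("ideal signals stay inside the sensor dynamic range", {
  spec <- sensor_spec()
  for (preset in c("healthy", "stroke")) {
    tpl <- gait_template(preset)
    for (aff in c(FALSE, TRUE)) {
      th <- generate_trajectory(tpl, n_strides = 3, affected = aff)
      tr <- inverse_strapdown(th, mag = TRUE)
      expect_lt(max(abs(tr$accel)), spec$accel_range)
      expect_lt(max(abs(tr$gyro)) * 180 / pi, spec$gyro_range)
      expect_true(all(attr(tr, "range_ok")))
    }
  }
})

test_that("sensor noise is seed-reproducible and mean-reverts to the bias", {
  tr <- stationary_trace(n = 3000)
  n1 <- add_sensor_noise(tr, seed = 11)
  n2 <- add_sensor_noise(tr, seed = 11)
  n3 <- add_sensor_noise(tr, seed = 12)
  expect_identical(n1$accel, n2$accel)
  expect_identical(n1$gyro, n2$gyro)
  expect_false(identical(n1$accel, n3$accel))
  # zero noise scale returns the input unchanged
  expect_identical(add_sensor_noise(tr, seed = 1, scale = 0)$accel, tr$accel)
  # long-run mean of the added signal approaches the drawn bias
  b <- attr(n1, "bias")
  expect_lt(max(abs(colMeans(n1$accel - tr$accel) - b$accel)),
            4 * 0.01 / sqrt(3000) + 1e-3)
  expect_lt(max(abs(colMeans(n1$gyro - tr$gyro) - b$gyro)),
            (4 * 0.1 / sqrt(3000) + 0.06) * pi / 180)
})

test_that("placement scenarios obey their motion geometry", {
  sc <- generate_placement_scenario(0.5, "translation", seed = 1)
  p1 <- as.matrix(sc$joints[, c("p1x", "p1y", "p1z")])
  d_imu <- sweep(sc$truth$pos, 2, sc$truth$pos[1, ])
  d_j1 <- unname(sweep(p1, 2, p1[1, ]))
  expect_equal(d_imu, d_j1, tolerance = 1e-12)

  scr <- generate_placement_scenario(0.5, "rotation", seed = 1)
  p2 <- as.matrix(scr$joints[, c("p2x", "p2y", "p2z")])
  v2 <- (p2[-1, ] - p2[-nrow(p2), ]) * scr$trace$fs
  v_imu <- (scr$truth$pos[-1, ] - scr$truth$pos[-nrow(p2), ]) * scr$trace$fs
  # IMU at mid-segment moves at half the speed of joint 2 (joint 1 fixed)
  expect_equal(sqrt(rowSums(v_imu^2)), 0.5 * sqrt(rowSums(v2^2)),
               tolerance = 1e-9)
  # seeds reproduce bitwise
  sc2 <- generate_placement_scenario(0.5, "rotation", seed = 1)
  expect_identical(scr$trace$accel, sc2$trace$accel)
})

test_that("stance-time asymmetry strictly degrades reported symmetry", {
  gs <- vapply(c(1, 0.9, 0.8), function(f) {
    tpl <- gait_template(asymmetry = list(stance_time = f))
    tr <- simulate_trial(tpl, n_strides = 10, noise = FALSE,
                         bilateral = TRUE)
    ms <- compute_all(analyze_trace(tr$traces$left),
                      analyze_trace(tr$traces$right))
    ms$symmetry$GS[["stance_ratio"]]
  }, numeric(1))
  expect_true(all(diff(gs) < 0))
})
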