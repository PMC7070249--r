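test_that("cadence, stride length and speed follow their definitions", {
  expect_equal(cadence(56, 60), 112)
  expect_equal(cadence(0, 60), 0)
  expect_equal(cadence(56, 120), 56)
  expect_error(cadence(10, 0), "positive")

  expect_equal(stride_length(c(0, 1.2, 2.4)), 1.2)
  expect_equal(stride_length(c(0.7, 0.7, 0.7)), 0)
  expect_error(stride_length(1.0), "at least 2")
  # the mean of successive differences telescopes
  set.seed(5)
  p <- cumsum(runif(9, 0.8, 1.4))
  expect_equal(stride_length(p) * (length(p) - 1), p[length(p)] - p[1])

  expect_equal(gait_speed(0, 15, 11.2), 15 / 11.2)
  expect_equal(gait_speed(3, 3, 10), 0)
  expect_error(gait_speed(0, 1, -1), "positive")
})

test_that("foot elevation is the per-stride maximum of corrected height", {
  expect_equal(max_foot_elevation(rep(0, 100)), 0)
  z <- c(rep(0, 10), 0.1, 0.2, 0.1, rep(0, 10), 0.15, 0.3, rep(0, 5))
  strides <- data.frame(stance_start = c(1, 14), next_start = c(14, 29))
  expect_equal(max_foot_elevation(z, strides), mean(c(0.2, 0.3)))
})

test_that("ankle ROM integrates the angular-rate difference", {
  n <- 201
  t <- seq(0, 1, length.out = n)
  dt <- t[2] - t[1]
  # shank-instep rate difference (pi/2) sin(2 pi t): angle swings 0.5 rad
  r <- ankle_rom((pi / 2) * sin(2 * pi * t), rep(0, n), dt)
  expect_equal(r$rom_deg, 0.5 * 180 / pi, tolerance = 1e-3)
  r0 <- ankle_rom(sin(t), sin(t), dt)
  expect_equal(r0$rom_deg, 0)
  expect_error(ankle_rom(1:5, 1:4, 0.01), "same length")
})

test_that("stance ratio and its complement partition the cycle", {
  expect_equal(stance_ratio(0.62, 0.38), 0.62)
  expect_equal(stance_ratio(0.5, 0.5), 0.5)
  expect_equal(stance_ratio(0.62, 0.38) + stance_ratio(0.38, 0.62), 1)
  expect_error(stance_ratio(0, 0.5), "positive")
})

test_that("gait symmetry is 1 at equality, bounded, and scale-invariant", {
  expect_equal(gait_symmetry(5, 5), 1)
  expect_equal(gait_symmetry(40, 60), 0.6)
  expect_equal(gait_symmetry(0, 10), -1)
  expect_error(gait_symmetry(0, 0), "positive")
  set.seed(7)
  for (i in 1:25) {
    Xa <- runif(1, 0.1, 10); Xs <- runif(1, 0.1, 10); c_ <- runif(1, 0.1, 9)
    expect_lte(gait_symmetry(Xa, Xs), 1)
    expect_equal(gait_symmetry(c_ * Xa, c_ * Xs), gait_symmetry(Xa, Xs),
                 tolerance = 1e-12)
  }
  # strictly decreasing in |Xa - Xs| at fixed sum
  s <- 10
  gs <- vapply(c(0, 1, 2, 3), function(d)
    gait_symmetry((s + d) / 2, (s - d) / 2), numeric(1))
  expect_true(all(diff(gs) < 0))
  # signed variant can exceed 1 when the affected side is smaller
  expect_gt(gait_symmetry(40, 60, signed = TRUE), 1)
})

test_that("all unilateral metrics are recovered across seeds", {
  tpl <- gait_template("healthy")
  for (seed in 1:10) {
    tr <- simulate_trial(tpl, n_strides = 12, seed = seed)
    m <- analyze_trace(tr$traces$left)$metrics
    tm <- tr$truth$left$metrics
    expect_lt(abs(m$stride_length_m - tm$stride_length_m), 0.02)
    expect_lt(abs(m$walking_speed_mps - tm$walking_speed_mps), 0.02)
    expect_lt(abs(m$max_foot_elevation_m - tm$max_foot_elevation_m), 0.02)
    expect_lt(abs(m$stance_ratio - tm$stance_ratio), 0.03)
    expect_lt(abs(m$cadence_spm - tm$cadence_spm), 2)
  }
})

test_that("bilateral symmetry reporting needs both limbs and ranks presets", {
  trb <- cached_sim("bil12", simulate_trial(n_strides = 12, seed = 5,
                                            bilateral = TRUE))
  left <- analyze_trace(trb$traces$left)
  right <- analyze_trace(trb$traces$right)
  ms <- compute_all(left, right)
  expect_gte(ms$symmetry$GS[["stance_ratio"]], 0.9)
  expect_error(compute_all(left, symmetry = TRUE), "both limbs")

  trs <- cached_sim("stroke12",
                    simulate_trial(gait_template("stroke"), n_strides = 12,
                                   seed = 6, bilateral = TRUE))
  ms_s <- compute_all(analyze_trace(trs$traces$left),
                      analyze_trace(trs$traces$right))
  expect_lt(ms_s$symmetry$GS[["stance_ratio"]],
            ms$symmetry$GS[["stance_ratio"]])
})
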