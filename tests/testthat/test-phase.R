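test_that("duration filter separates stride-scale phases from blips", {
  f <- kmeans_duration_filter(c(0.60, 0.62, 0.61, 0.05, 0.04))
  expect_equal(f$accepted, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(c(f$d_min, f$d_max), c(0.60, 0.62))
  expect_true(f$filtered)
})

test_that("homogeneous durations are all accepted", {
  f <- kmeans_duration_filter(rep(0.61, 6))
  expect_true(all(f$accepted))
  expect_equal(f$d_min, f$d_max)
  expect_false(f$filtered)
  expect_warning(f1 <- kmeans_duration_filter(0.6), "fewer than 2")
  expect_true(all(f1$accepted))
})

test_that("the 1-D 2-means filter attains the exhaustive optimal partition", {
  set.seed(31)
  for (rep in 1:15) {
    n_true <- sample(2:8, 1)
    n_blip <- sample(1:4, 1)
    d <- c(rnorm(n_true, 0.62, 0.03), runif(n_blip, 0.02, 0.10))
    d <- d[sample(length(d))]
    f <- kmeans_duration_filter(d)
    ref <- brute_force_2partition(d)
    expect_equal(f$accepted, ref$sel)
  }
})

test_that("spurious short stance blips are rejected without losing strides", {
  tr <- healthy_trial_8()
  tl <- tr$traces$left
  m <- detect_stance(tl)
  seg0 <- segment_gait(m, tl$dt)
  # inject 30 ms spurious stance blips into the middle of three swings
  iv <- stance_intervals(m)
  m2 <- m
  for (j in 2:4) {
    mid <- (iv$end[j] + iv$start[j + 1]) %/% 2
    m2$mask[mid:(mid + 2)] <- TRUE
  }
  seg2 <- segment_gait(m2, tl$dt)
  expect_equal(seg2$n_steps, seg0$n_steps)
  blips <- seg2$stance$duration < 0.05 & !seg2$stance$boundary
  expect_true(all(!seg2$stance$accepted[blips]))
})

test_that("step counting matches the simulated stride count", {
  expect_equal(count_steps(stationary_trace()), 0L)
  for (case in list(c(10, 1), c(25, 2), c(40, 3))) {
    tr <- simulate_trial(n_strides = case[1], seed = case[2])
    expect_equal(count_steps(tr$traces$left), as.integer(case[1]))
  }
  # and on clean (noise-free) output
  tr <- simulate_trial(n_strides = 12, noise = FALSE)
  expect_equal(count_steps(tr$traces$left), 12L)
})

test_that("step count decays to zero as Td shrinks and is exact at default", {
  tl <- healthy_trial_8()$traces$left
  counts <- vapply(c(3, 1, 0.2, 0.05), function(td)
    count_steps(tl, Td = td), integer(1))
  expect_equal(counts[1], 8L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0L)
})

test_that("sub-phases tile the stance and foot-flat dominates", {
  a <- healthy_analysis_8()
  parts <- stance_subphases(a)
  strides <- a$segmentation$strides
  ff <- rep(NA_real_, length(parts))
  for (i in seq_along(parts)) {
    d <- parts[[i]]
    stance_n <- strides$stance_end[i] - strides$stance_start[i]
    expect_equal(sum(d$end - d$start), stance_n)
    if (nrow(d) == 3) ff[i] <- d$duration[2] / sum(d$duration)
  }
  expect_gt(sum(!is.na(ff)), length(parts) / 2)
  expect_gt(stats::median(ff, na.rm = TRUE), 0.4)
})

test_that("a gyro with no interior zero-crossing is left unpartitioned", {
  g <- sin(pi * seq(0, 1, length.out = 80)) + 0.05 # strictly positive
  expect_warning(d <- partition_subphases(g, 0.01), "zero-crossing")
  expect_equal(nrow(d), 1L)
  expect_equal(d$kind, "stance")
})
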