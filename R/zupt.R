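#' Detect stance (zero-velocity) candidates
#'
#' A sample is a stance candidate when the windowed detection statistic falls
#' below the threshold `Td`. The per-sample statistic combines the normalized
#' accelerometer-magnitude deviation and the gyroscope magnitude,
#' `s_i = |'||a_i|| - g| / sigma_a + ||w_i|| / sigma_w`,
#' with the normalizers taken from the sensor's bias stability (defaults
#' 0.02 m/s^2 and 1 deg/s). The statistic is averaged over a centred window
#' of `Wd` samples; because a centred mean erodes the edges of quiet
#' intervals by up to half a window, each detected run is then refined
#' outward while the raw per-sample statistic stays below `Td`
#' (hysteresis-style boundary recovery).
#'
#' When the trace starts at standstill the gyro bias is subtracted and the
#' gravity reference is the measured standstill magnitude (see
#' [calibrate_trace()]); otherwise 9.81 m/s^2 and zero bias are used.
#'
#' @param trace an [imu_trace()].
#' @param Wd detection window length in samples (>= 1).
#' @param Td dimensionless detection threshold (> 0).
#' @param calibration optional [calibrate_trace()] result; computed from the
#'   trace when `NULL`.
#' @param sigma_a,sigma_w statistic normalizers (m/s^2 and rad/s).
#' @param refine logical; apply the boundary refinement step.
#' @return Object of class `stance_mask`: list with `mask` (logical per
#'   sample), `stat` (per-sample statistic), `stat_win` (windowed statistic),
#'   `Wd`, `Td`.
#' @export
detect_stance <- function(trace, Wd = 15, Td = 3, calibration = NULL,
                          sigma_a = 0.02, sigma_w = pi / 180,
                          refine = TRUE) {
  n <- length(trace$t)
  if (Wd < 1) stop("Wd must be >= 1")
  if (Wd > n) stop("Wd is larger than the trace")
  if (Td <= 0) stop("Td must be > 0")
  if (is.null(calibration)) {
    calibration <- suppressWarnings(calibrate_trace(trace))
  }
  g_ref <- calibration$g_ref
  w <- sweep(trace$gyro, 2, calibration$gyro_bias)
  s <- abs(sqrt(rowSums(trace$accel^2)) - g_ref) / sigma_a +
    sqrt(rowSums(w^2)) / sigma_w
  S <- roll_mean(s, Wd)
  mask <- S < Td
  if (refine && any(mask)) mask <- refine_runs(mask, s < Td)
  structure(list(mask = mask, stat = s, stat_win = S, Wd = Wd, Td = Td),
            class = "stance_mask")
}

# centred rolling mean with partial windows at the edges
roll_mean <- function(x, w) {
  n <- length(x)
  half <- (w - 1) %/% 2
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (w - 1 - half), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# extend every TRUE run of `mask` outward while `quiet` holds per sample
refine_runs <- function(mask, quiet) {
  n <- length(mask)
  out <- mask
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in which(r$values)) {
    k <- starts[j] - 1
    while (k >= 1 && quiet[k] && !out[k]) {
      out[k] <- TRUE
      k <- k - 1
    }
    k <- ends[j] + 1
    while (k <= n && quiet[k] && !out[k]) {
      out[k] <- TRUE
      k <- k + 1
    }
  }
  out
}

#' Maximal runs of a stance mask as intervals
#'
#' @param mask logical vector or a `stance_mask`.
#' @return Data frame with half-open sample intervals `start`, `end`
#'   (1-based; `end` is one past the last stance sample) and `n` samples.
#' @export
stance_intervals <- function(mask) {
  if (inherits(mask, "stance_mask")) mask <- mask$mask
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep] + 1L,
             n = r$lengths[keep])
}

#' Per-cycle accelerometer bias from end-of-swing velocity
#'
#' The foot is known to be stationary at the end of every swing; a constant
#' acceleration bias over the cycle therefore shows up as a non-zero
#' integrated velocity at swing end and is recovered as
#' `epsilon = v(T_sw) / T_sw` (componentwise, navigation frame).
#'
#' @param v_end velocity at swing end (m/s) from raw integration started at
#'   zero at swing begin.
#' @param T_sw swing duration in seconds, > 0.
#' @return List of class `bias_estimate`: `epsilon` (m/s^2), `T_sw`, `v_end`.
#' @export
estimate_cycle_bias <- function(v_end, T_sw) {
  if (!is.numeric(T_sw) || length(T_sw) != 1 || T_sw <= 0) {
    stop("T_sw must be a positive scalar")
  }
  structure(list(epsilon = v_end / T_sw, T_sw = T_sw, v_end = v_end),
            class = "bias_estimate")
}

#' Linearly de-drift the velocity of one swing
#'
#' Subtracts `epsilon * (t - t_start)` inside the swing so that the corrected
#' velocity is exactly zero at swing end, per the constant-bias model.
#'
#' @param v_raw m x 3 matrix of raw swing velocities (first row at swing
#'   start).
#' @param t_rel elapsed time since swing start for each row (s).
#' @param bias a [estimate_cycle_bias()] result (or a length-3 epsilon).
#' @return m x 3 matrix of corrected velocities.
#' @export
correct_velocity <- function(v_raw, t_rel, bias) {
  eps <- if (inherits(bias, "bias_estimate")) bias$epsilon else bias
  v_raw - outer(t_rel, eps)
}

#' Zero-velocity-corrected navigation states for a full trace
#'
#' Runs the per-cycle drift correction over every swing interval of the
#' stance mask: the velocity is re-zeroed at each swing start, integrated
#' over the swing, the constant-bias term estimated from the end-of-swing
#' velocity is removed, and velocity is pinned to exactly zero throughout
#' every stance interval. Position is the trapezoidal integral of the
#' corrected velocity (constant during stance). With `flat_ground = TRUE`
#' (the default; the method targets level-ground walking) the net vertical
#' displacement of each swing is additionally de-drifted to zero, which
#' stops the residual levelling tilt from accumulating height error across
#' strides.
#'
#' @param trace an [imu_trace()].
#' @param mask a [detect_stance()] result (computed with defaults if `NULL`).
#' @param calibration optional [calibrate_trace()] result.
#' @param p0 initial position (m).
#' @param flat_ground logical; apply the per-swing height update.
#' @return List of class `zupt_result`: `nav` (data frame `t, qw..qz, vx..vz,
#'   px..pz`), `mask`, `intervals` (stance intervals), `bias` (per-swing
#'   [estimate_cycle_bias()] list), `raw` (uncorrected strapdown data frame),
#'   `calibration`.
#' @export
zupt_correct <- function(trace, mask = NULL, calibration = NULL,
                         p0 = c(0, 0, 0), flat_ground = TRUE) {
  if (is.null(calibration)) {
    calibration <- suppressWarnings(calibrate_trace(trace))
  }
  if (is.null(mask)) mask <- detect_stance(trace, calibration = calibration)
  # zero-angular-rate update: the foot is rotation-free through mid-stance,
  # so the mean mid-stance gyro over the whole trial re-estimates the bias
  # far more tightly than the initial standstill alone. Without it the
  # residual vertical-axis bias drifts the (otherwise unobservable) heading
  # and lateral position error grows quadratically with distance walked.
  zaru <- refine_gyro_bias(trace, mask)
  if (!is.null(zaru)) calibration$gyro_bias <- zaru
  raw <- strapdown_integrate(trace, q0 = calibration$q0,
                             gyro_bias = calibration$gyro_bias,
                             g_ref = calibration$g_ref)
  a_nav <- attr(raw, "a_nav")
  n <- length(trace$t)
  dt <- trace$dt
  iv <- stance_intervals(mask)
  v <- matrix(0, n, 3)
  biases <- list()
  if (nrow(iv) >= 1) {
    # swings are the gaps between consecutive stance runs
    swings <- if (nrow(iv) >= 2) {
      data.frame(start = iv$end[-nrow(iv)], end = iv$start[-1])
    } else {
      data.frame(start = integer(0), end = integer(0))
    }
    # leading / trailing motion (before first or after last stance run) is
    # integrated without an end-of-swing anchor: de-drift is not possible
    lead <- if (iv$start[1] > 1) data.frame(start = 1L, end = iv$start[1]) else NULL
    tail_ <- if (iv$end[nrow(iv)] <= n) {
      data.frame(start = iv$end[nrow(iv)], end = n + 1L)
    } else NULL
    for (j in seq_len(nrow(swings))) {
      i0 <- swings$start[j]           # first airborne sample
      i1 <- swings$end[j]             # first sample of next stance (v = 0)
      idx <- (i0 - 1):i1              # include last stance sample as v=0 anchor
      vsw <- cumtrapz_mat(a_nav[idx, , drop = FALSE], dt, c(0, 0, 0))
      T_sw <- (length(idx) - 1) * dt
      b <- estimate_cycle_bias(vsw[nrow(vsw), ], T_sw)
      t_rel <- (seq_along(idx) - 1) * dt
      vc <- correct_velocity(vsw, t_rel, b)
      v[idx, ] <- vc
      v[i1, ] <- 0 # exact by construction; enforce against round-off
      biases[[length(biases) + 1]] <- b
    }
    for (edge in list(lead, tail_)) {
      if (!is.null(edge) && edge$end - edge$start > 1) {
        idx <- edge$start:(edge$end - 1)
        v[idx, ] <- cumtrapz_mat(a_nav[idx, , drop = FALSE], dt, c(0, 0, 0))
      }
    }
    v[mask$mask, ] <- 0
  } else {
    v <- cumtrapz_mat(a_nav, dt, c(0, 0, 0))
  }
  if (flat_ground && nrow(iv) >= 2) {
    for (j in seq_len(nrow(iv) - 1)) {
      i0 <- iv$end[j] - 1L
      i1 <- iv$start[j + 1]
      dz <- sum((v[i0:(i1 - 1), 3] + v[(i0 + 1):i1, 3]) / 2 * dt)
      m <- i1 - i0
      if (m < 2) next
      idx <- i0:i1
      # subtracting this constant from the airborne samples removes exactly
      # dz from the trapezoidal integral across the swing
      v[idx, 3] <- v[idx, 3] - dz / (dt * (m - 1)) * !(mask$mask[idx])
    }
  }
  p <- reconstruct_position(v, dt, p0)
  nav <- raw
  nav[, c("vx", "vy", "vz")] <- v
  nav[, c("px", "py", "pz")] <- p
  structure(list(nav = nav, mask = mask, intervals = iv, bias = biases,
                 raw = raw, calibration = calibration),
            class = "zupt_result")
}

# mean gyro over the central 25-70% of each stance run (the foot-flat
# portion, clear of heel-strike and push-off rotations); NULL if the mask
# offers fewer than 50 usable samples
refine_gyro_bias <- function(trace, mask) {
  iv <- stance_intervals(mask)
  # only runs long enough to be real stances (not detector fragments)
  iv <- iv[iv$n * trace$dt >= 0.25, , drop = FALSE]
  idx <- unlist(lapply(seq_len(nrow(iv)), function(j) {
    n <- iv$end[j] - iv$start[j]
    lo <- iv$start[j] + floor(0.25 * n)
    hi <- iv$start[j] + floor(0.70 * n)
    if (hi > lo) lo:hi else integer(0)
  }))
  if (length(idx) < 50) return(NULL)
  colMeans(trace$gyro[idx, , drop = FALSE])
}

#' Position from corrected velocity
#'
#' Trapezoidal integral of the drift-corrected velocity; position is constant
#' wherever the velocity is zero (stance).
#'
#' @param v_corr n x 3 matrix of corrected velocity (m/s).
#' @param dt sample interval (s).
#' @param p0 initial position (m).
#' @return n x 3 matrix of positions.
#' @export
reconstruct_position <- function(v_corr, dt, p0 = c(0, 0, 0)) {
  cumtrapz_mat(as.matrix(v_corr), dt, p0)
}
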