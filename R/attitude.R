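#' Initial attitude from accelerometer levelling
#'
#' Roll and pitch are recovered from the mean specific force measured while
#' the sensor is at rest (the accelerometer then reads the gravity reaction,
#' i.e. "up" in the body frame). Yaw is left at zero: no magnetometer fusion
#' is performed, and no alignment movements are required of the wearer.
#'
#' @param a_mean mean specific-force vector (m/s^2) over a quiescent period.
#' @return Unit quaternion (body to navigation) rotating `a_mean` onto the
#'   navigation vertical, with zero yaw.
#' @export
level_quaternion <- function(a_mean) {
  u <- a_mean / sqrt(sum(a_mean^2))
  z <- c(0, 0, 1)
  d <- sum(u * z)
  if (d > 1 - 1e-12) return(quat_identity())
  if (d < -1 + 1e-12) return(c(0, 1, 0, 0)) # upside down: 180 deg about x
  axis <- c(u[2] * z[3] - u[3] * z[2],
            u[3] * z[1] - u[1] * z[3],
            u[1] * z[2] - u[2] * z[1])
  quat_from_axis_angle(axis, acos(max(-1, min(1, d))))
}

#' Standstill calibration of an IMU trace
#'
#' Uses an initial quiescent window (the wearer standing still before the
#' walk) to estimate the static gyroscope bias, the local gravity reading,
#' and the initial attitude by accelerometer levelling. These estimates feed
#' the stance detector and the strapdown integration.
#'
#' @param trace an [imu_trace()].
#' @param window_s length of the calibration window in seconds (taken from
#'   the start of the trace).
#' @param max_gyro_sd quiescence check: if the per-axis gyro standard
#'   deviation inside the window exceeds this (rad/s) the trace is deemed to
#'   start in motion and neutral defaults are returned with a warning.
#' @return A list of class `imu_calibration`: `q0` (levelled initial
#'   attitude), `gyro_bias` (rad/s), `g_ref` (measured gravity magnitude,
#'   m/s^2), `quiescent` (logical), `window` (sample index range used).
#' @export
calibrate_trace <- function(trace, window_s = 1.5, max_gyro_sd = 0.05) {
  n_win <- max(2L, min(length(trace$t), round(window_s / trace$dt)))
  idx <- seq_len(n_win)
  gyro_sd <- apply(trace$gyro[idx, , drop = FALSE], 2, stats::sd)
  a_mean <- colMeans(trace$accel[idx, , drop = FALSE])
  quiescent <- all(gyro_sd < max_gyro_sd)
  if (!quiescent) {
    warning("trace does not start at standstill; using neutral calibration")
    return(structure(
      list(q0 = level_quaternion(a_mean), gyro_bias = c(0, 0, 0),
           g_ref = GRAVITY, quiescent = FALSE, window = range(idx)),
      class = "imu_calibration"))
  }
  structure(
    list(q0 = level_quaternion(a_mean),
         gyro_bias = colMeans(trace$gyro[idx, , drop = FALSE]),
         g_ref = mean(sqrt(rowSums(trace$accel[idx, , drop = FALSE]^2))),
         quiescent = TRUE, window = range(idx)),
    class = "imu_calibration")
}

#' Integrate the attitude quaternion over a trace
#'
#' Propagates `dq/dt = q (0, omega) / 2` sample by sample with
#' [rk4_attitude_step()], renormalizing at every step.
#'
#' @param trace an [imu_trace()].
#' @param q0 initial unit quaternion (body to navigation).
#' @param gyro_bias length-3 bias (rad/s) subtracted from the gyro channel
#'   before integration.
#' @return n x 4 matrix of unit quaternions, row k the attitude at `t[k]`.
#' @export
integrate_attitude <- function(trace, q0 = quat_identity(),
                               gyro_bias = c(0, 0, 0)) {
  n <- length(trace$t)
  w <- sweep(trace$gyro, 2, gyro_bias)
  q <- matrix(0, n, 4)
  q[1, ] <- quat_normalize(q0)
  dt <- trace$dt
  for (k in seq_len(n - 1)) {
    q[k + 1, ] <- rk4_attitude_step(q[k, ], w[k, ], w[k + 1, ], dt)
  }
  q
}

#' Raw strapdown integration of an IMU trace
#'
#' Integrates the full strapdown state: attitude by RK4 quaternion
#' propagation, then navigation-frame velocity and position by the
#' trapezoidal rule, with the gravity vector removed from the rotated
#' specific force. No zero-velocity correction is applied, so the output
#' drifts with sensor bias — this is the uncorrected reference against which
#' the ZUPT stage is judged.
#'
#' @param trace an [imu_trace()].
#' @param q0 initial attitude quaternion; if `NULL`, estimated by
#'   [calibrate_trace()] levelling.
#' @param v0,p0 initial velocity (m/s) and position (m), navigation frame.
#' @param gyro_bias length-3 gyro bias (rad/s) subtracted before integration.
#' @param g_ref gravity magnitude subtracted on the navigation z axis.
#' @return A data frame with columns `t, qw, qx, qy, qz, vx, vy, vz, px, py,
#'   pz` and attribute `a_nav` (n x 3 matrix of gravity-compensated
#'   navigation-frame acceleration).
#' @export
strapdown_integrate <- function(trace, q0 = NULL, v0 = c(0, 0, 0),
                                p0 = c(0, 0, 0), gyro_bias = c(0, 0, 0),
                                g_ref = GRAVITY) {
  if (is.null(q0)) {
    cal <- calibrate_trace(trace)
    q0 <- cal$q0
    gyro_bias <- cal$gyro_bias
    g_ref <- cal$g_ref
  }
  n <- length(trace$t)
  dt <- trace$dt
  q <- integrate_attitude(trace, q0, gyro_bias)
  a_nav <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    a_nav[k, ] <- rotate_to_nav(q[k, ], trace$accel[k, ]) - c(0, 0, g_ref)
  }
  v <- cumtrapz_mat(a_nav, dt, v0)
  p <- cumtrapz_mat(v, dt, p0)
  out <- data.frame(t = trace$t,
                    qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4],
                    vx = v[, 1], vy = v[, 2], vz = v[, 3],
                    px = p[, 1], py = p[, 2], pz = p[, 3])
  attr(out, "a_nav") <- a_nav
  out
}

# cumulative trapezoidal integral of each column, plus initial value
cumtrapz_mat <- function(x, dt, x0 = c(0, 0, 0)) {
  n <- nrow(x)
  out <- matrix(rep(x0, each = n), n, ncol(x))
  if (n > 1) {
    inc <- (x[-n, , drop = FALSE] + x[-1, , drop = FALSE]) * dt / 2
    out[-1, ] <- out[-1, , drop = FALSE] + apply(inc, 2, cumsum)
  }
  out
}

cumtrapz_vec <- function(x, dt, x0 = 0) {
  c(x0, x0 + cumsum((x[-length(x)] + x[-1]) * dt / 2))
}
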