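#' Quaternion utilities
#'
#' Quaternions are plain numeric vectors of length 4 in Hamilton convention,
#' scalar first: `c(w, x, y, z)`. A unit quaternion represents the rotation
#' from the sensor (body) frame to the navigation frame.
#'
#' @name quaternion
NULL

#' Identity quaternion
#' @return `c(1, 0, 0, 0)`.
#' @export
quat_identity <- function() c(1, 0, 0, 0)

#' Hamilton product of two quaternions
#'
#' @param a,b numeric length-4 quaternions, scalar first.
#' @return The Hamilton product `a %*% b` as a length-4 numeric vector. The
#'   product of two unit quaternions is unit.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion conjugate
#' @param q numeric length-4 quaternion.
#' @return The conjugate `(w, -x, -y, -z)`; the inverse for unit quaternions.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Normalize a quaternion to unit length
#' @param q numeric length-4 quaternion.
#' @return `q / |q|`.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Quaternion from an axis-angle rotation
#' @param axis rotation axis (length-3, need not be unit).
#' @param angle rotation angle in radians.
#' @return Unit quaternion rotating by `angle` about `axis`.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis * axis))
  if (n == 0) return(quat_identity())
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

#' Rotate a body-frame vector into the navigation frame
#'
#' Applies `q (0, v) q*`, i.e. the body-to-navigation rotation encoded by the
#' attitude quaternion. Gravity is not removed here.
#'
#' @param q unit quaternion (body to navigation).
#' @param a_body length-3 vector in the body frame (e.g. specific force,
#'   m/s^2).
#' @return The vector expressed in the navigation frame.
#' @export
rotate_to_nav <- function(q, a_body) {
  p <- quat_multiply(quat_multiply(q, c(0, a_body)), quat_conjugate(q))
  p[2:4]
}

#' Rotation matrix of a quaternion
#'
#' @param q unit quaternion (body to navigation).
#' @return 3x3 rotation matrix `R` with `R %*% v_body = v_nav`.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

# time derivative of the attitude quaternion: dq/dt = q (0, w) / 2
quat_deriv <- function(q, w) {
  0.5 * quat_multiply(q, c(0, w))
}

#' Advance the attitude quaternion one step by fourth-order Runge-Kutta
#'
#' Integrates `dq/dt = q (0, omega) / 2` across one sample interval. The
#' gyroscope samples at the start and end of the step are linearly
#' interpolated to supply the midpoint rate required by RK4, giving a local
#' truncation error of O(dt^5) for smooth angular velocity.
#'
#' @param q unit attitude quaternion at step start.
#' @param w0,w1 gyroscope samples (rad/s, body frame) at step start and end.
#' @param dt step length in seconds, > 0.
#' @return The advanced quaternion, renormalized to unit length.
#' @export
rk4_attitude_step <- function(q, w0, w1, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("dt must be a positive scalar")
  }
  wm <- (w0 + w1) / 2
  k1 <- quat_deriv(q, w0)
  k2 <- quat_deriv(q + dt / 2 * k1, wm)
  k3 <- quat_deriv(q + dt / 2 * k2, wm)
  k4 <- quat_deriv(q + dt * k3, w1)
  quat_normalize(q + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
}
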