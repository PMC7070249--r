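#' IMU position along a limb segment from the installation ratio
#'
#' The IMU sits on the straight segment between two adjacent joints at the
#' fixed ratio `k`: `p(t) = p1(t) + k (p2(t) - p1(t))` (0 = at joint 1,
#' 1 = at joint 2). Affine in `k` at every sample.
#'
#' @param k installation ratio (dimensionless).
#' @param joints data frame with columns `p1x, p1y, p1z, p2x, p2y, p2z`
#'   (and optionally `t`).
#' @return n x 3 matrix of IMU positions.
#' @export
imu_position_from_ratio <- function(k, joints) {
  p1 <- as.matrix(joints[, c("p1x", "p1y", "p1z")])
  p2 <- as.matrix(joints[, c("p2x", "p2y", "p2z")])
  unname(p1 + k * (p2 - p1))
}

#' Kalman estimate of the IMU installation ratio
#'
#' Estimates where along a limb segment the IMU is mounted, fusing the
#' inertial stream with the trajectories of the two adjacent joints. The
#' state is `(v, s, k)`: inertial velocity, inertial displacement since the
#' start, and the (constant) installation ratio. The process model
#' integrates the gravity-compensated navigation-frame acceleration
#' (`dv/dt = a`, `ds/dt = v`, `dk/dt = 0`, discretized to second order);
#' the observation equates the measured joint-1 displacement with
#' `k [(p1(t)-p1(0)) - (p2(t)-p2(0))] + s(t)`. With the measured joint
#' displacements treated as known regressors the observation is linear in
#' the state, and the covariance is propagated in Joseph form so it stays
#' symmetric positive semi-definite.
#'
#' Under pure translation the two joint displacements coincide, the `k`
#' column of the observation vanishes, and the `k` variance cannot shrink:
#' the estimate is returned with `unobservable = TRUE` rather than an error.
#'
#' @param trace an [imu_trace()] of the segment-mounted IMU.
#' @param joints data frame `t, p1x..p1z, p2x..p2z`, same time base as the
#'   trace.
#' @param q n x 4 matrix of attitude quaternions (body to navigation); if
#'   `NULL`, integrated from the trace with [integrate_attitude()] after
#'   standstill calibration.
#' @param k0,k_sigma prior mean and sigma of the ratio (default 0.5 +/- 0.5,
#'   an uninformative mid-segment prior).
#' @param joint_noise_m measurement noise sigma of the joint positions (m).
#' @param accel_noise process noise sigma on velocity per sqrt(s)
#'   (m/s^2).
#' @return List of class `placement_estimate`: `k` (final estimate),
#'   `k_var`, `k_prior_var`, `unobservable` (logical), `k_path` (per-step
#'   estimates), `innovations` (n x 3 matrix).
#' @export
kalman_install_ratio <- function(trace, joints, q = NULL,
                                 k0 = 0.5, k_sigma = 0.5,
                                 joint_noise_m = 1e-3,
                                 accel_noise = 0.02) {
  n <- length(trace$t)
  if (nrow(joints) != n) stop("trace and joint trajectories differ in length")
  if (is.null(q)) {
    cal <- suppressWarnings(calibrate_trace(trace))
    q <- integrate_attitude(trace, cal$q0, cal$gyro_bias)
  }
  dt <- trace$dt
  a_nav <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a_nav[i, ] <- rotate_to_nav(q[i, ], trace$accel[i, ]) - c(0, 0, GRAVITY)
  }
  p1 <- as.matrix(joints[, c("p1x", "p1y", "p1z")])
  p2 <- as.matrix(joints[, c("p2x", "p2y", "p2z")])
  d1 <- sweep(p1, 2, p1[1, ])
  d2 <- sweep(p2, 2, p2[1, ])

  x <- c(0, 0, 0, 0, 0, 0, k0)
  P <- diag(c(rep(1e-4, 3), rep(1e-4, 3), k_sigma^2))
  k_prior_var <- P[7, 7]
  F_ <- diag(7)
  F_[4, 1] <- F_[5, 2] <- F_[6, 3] <- dt
  Q <- diag(c(rep((accel_noise * dt)^2, 3),
              rep((0.5 * accel_noise * dt^2)^2, 3), 0))
  R <- diag(max(joint_noise_m^2, 1e-12), 3)
  I7 <- diag(7)
  k_path <- numeric(n)
  innov <- matrix(0, n, 3)
  k_path[1] <- x[7]
  for (i in 2:n) {
    # velocity increment by 2-step Adams-Moulton where possible: the plain
    # trapezoid leaves a constant O(dt^2) velocity offset (Euler-Maclaurin
    # boundary term) that the filter would misattribute to k
    inc <- if (i >= 3) {
      dt * (5 * a_nav[i, ] + 8 * a_nav[i - 1, ] - a_nav[i - 2, ]) / 12
    } else {
      dt * (a_nav[i - 1, ] + a_nav[i, ]) / 2
    }
    x_new <- x
    x_new[1:3] <- x[1:3] + inc
    x_new[4:6] <- x[4:6] + x[1:3] * dt + inc * dt / 2
    x <- x_new
    P <- F_ %*% P %*% t(F_) + Q
    # observation: d1 = k (d1 - d2) + s
    H <- cbind(matrix(0, 3, 3), diag(3), d1[i, ] - d2[i, ])
    y <- d1[i, ]
    nu <- y - as.numeric(H %*% x)
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    x <- x + as.numeric(K %*% nu)
    IKH <- I7 - K %*% H
    P <- IKH %*% P %*% t(IKH) + K %*% R %*% t(K)
    P <- (P + t(P)) / 2
    k_path[i] <- x[7]
    innov[i, ] <- nu
  }
  structure(list(k = x[7], k_var = P[7, 7], k_prior_var = k_prior_var,
                 unobservable = P[7, 7] >= 0.99 * k_prior_var,
                 k_path = k_path, innovations = innov, P = P),
            class = "placement_estimate")
}

#' @export
print.placement_estimate <- function(x, ...) {
  cat(sprintf("<placement_estimate> k = %.4f (sd %.2g)%s\n",
              x$k, sqrt(x$k_var),
              if (x$unobservable) " [unobservable: pure translation]" else ""))
  invisible(x)
}
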