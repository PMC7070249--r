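#' Construct an IMU trace
#'
#' Container for the uniformly sampled tri-axial streams of one sensor node.
#' Internally the package works in SI units throughout: seconds, m/s^2 for
#' specific force (gravity included), rad/s for angular rate, and microtesla
#' for the optional magnetometer channel. Degrees appear only at I/O
#' boundaries and in reports.
#'
#' @param t numeric vector of timestamps in seconds, strictly increasing with
#'   a constant step (within 1e-6 s).
#' @param accel n x 3 matrix of specific force, m/s^2 (gravity included).
#' @param gyro n x 3 matrix of angular rate, rad/s.
#' @param mag optional n x 3 matrix of magnetic field, microtesla.
#' @param node_id text label of the sensor node.
#' @param side one of `"left"`, `"right"`, `"unknown"`.
#' @param placement one of `"instep"`, `"shank"`, `"unknown"`.
#' @param spec a [sensor_spec()] used for dynamic-range validation.
#' @param validate set `FALSE` to skip validation (internal use).
#' @return An object of class `imu_trace`: a list with the fields above plus
#'   `dt` (sample interval) and `fs` (sample rate). Samples outside the
#'   sensor's dynamic range are flagged in the `range_ok` attribute and
#'   reported as a warning, never silently clipped.
#' @export
imu_trace <- function(t, accel, gyro, mag = NULL,
                      node_id = "imu", side = "unknown",
                      placement = "unknown", spec = sensor_spec(),
                      validate = TRUE) {
  accel <- as_matrix3(accel, "accel")
  gyro <- as_matrix3(gyro, "gyro")
  if (!is.null(mag)) mag <- as_matrix3(mag, "mag")
  side <- match.arg(side, c("left", "right", "unknown"))
  placement <- match.arg(placement, c("instep", "shank", "unknown"))
  n <- length(t)
  if (n < 2) stop("an imu_trace needs at least 2 samples")
  if (nrow(accel) != n || nrow(gyro) != n || (!is.null(mag) && nrow(mag) != n)) {
    stop("all channels must have the same length as t")
  }
  dts <- diff(t)
  if (any(dts <= 0)) stop("non-monotonic timestamps")
  dt <- stats::median(dts)
  if (validate && any(abs(dts - dt) > 1e-6)) {
    stop("timestamps are not uniform: sample interval varies by more than 1e-6 s")
  }
  x <- structure(
    list(t = as.numeric(t), accel = accel, gyro = gyro, mag = mag,
         node_id = node_id, side = side, placement = placement,
         dt = dt, fs = 1 / dt),
    class = "imu_trace")
  if (validate) {
    ok <- abs(accel) <= spec$accel_range &
      abs(gyro) <= spec$gyro_range * pi / 180
    if (!is.null(mag)) ok <- cbind(ok, abs(mag) <= spec$mag_range)
    bad <- !apply(ok, 1, all)
    attr(x, "range_ok") <- !bad
    if (any(bad)) {
      warning(sprintf(
        "%d of %d samples exceed the sensor dynamic range (flagged, not clipped)",
        sum(bad), n))
    }
  }
  x
}

#' @export
print.imu_trace <- function(x, ...) {
  cat(sprintf(
    "<imu_trace> node '%s' (%s %s): %d samples @ %.6g Hz, %.2f s%s\n",
    x$node_id, x$side, x$placement, length(x$t), x$fs,
    diff(range(x$t)), if (is.null(x$mag)) "" else ", with magnetometer"))
  invisible(x)
}

as_matrix3 <- function(m, name) {
  m <- as.matrix(m)
  if (ncol(m) != 3) stop(sprintf("%s must have 3 columns", name))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Sensor performance specification
#'
#' Dynamic ranges, bandwidths, and bias stabilities of a MEMS inertial node,
#' with defaults matching the consumer-grade unit the package targets:
#' accelerometer +/-50 m/s^2 (30 Hz bandwidth, bias 1-sigma 0.02 m/s^2),
#' gyroscope +/-1200 deg/s (40 Hz, 1 deg/s), magnetometer +/-750 uT (10 Hz,
#' 0.1 uT). The default sample rate is 100 Hz.
#'
#' @param accel_range m/s^2. @param gyro_range deg/s. @param mag_range uT.
#' @param accel_bandwidth,gyro_bandwidth,mag_bandwidth Hz.
#' @param accel_bias_sigma m/s^2 (1 sigma). @param gyro_bias_sigma deg/s.
#' @param mag_bias_sigma uT.
#' @param sample_rate Hz.
#' @return Object of class `sensor_spec`.
#' @export
sensor_spec <- function(accel_range = 50, gyro_range = 1200, mag_range = 750,
                        accel_bandwidth = 30, gyro_bandwidth = 40,
                        mag_bandwidth = 10,
                        accel_bias_sigma = 0.02, gyro_bias_sigma = 1,
                        mag_bias_sigma = 0.1, sample_rate = 100) {
  vals <- c(accel_range, gyro_range, mag_range, accel_bandwidth,
            gyro_bandwidth, mag_bandwidth, accel_bias_sigma, gyro_bias_sigma,
            mag_bias_sigma, sample_rate)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all sensor_spec values must be positive and finite")
  }
  structure(
    list(accel_range = accel_range, gyro_range = gyro_range,
         mag_range = mag_range, accel_bandwidth = accel_bandwidth,
         gyro_bandwidth = gyro_bandwidth, mag_bandwidth = mag_bandwidth,
         accel_bias_sigma = accel_bias_sigma,
         gyro_bias_sigma = gyro_bias_sigma,
         mag_bias_sigma = mag_bias_sigma, sample_rate = sample_rate),
    class = "sensor_spec")
}

# gravity magnitude used throughout (m/s^2), navigation frame z up
GRAVITY <- 9.81
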