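#' Full single-foot gait analysis
#'
#' Runs the complete chain on one foot-mounted trace: standstill
#' calibration, RK4 strapdown integration, stance detection, per-cycle
#' zero-velocity drift correction, k-means-validated cycle segmentation, and
#' the spatio-temporal metrics. The forward direction is defined per trial
#' as the unit horizontal displacement between the first and last accepted
#' touchdowns.
#'
#' @param trace an [imu_trace()] of a foot-mounted sensor.
#' @param Wd,Td stance-detector window (samples) and threshold.
#' @param flat_ground apply the per-swing height update (level walking).
#' @param steps_per_stride cadence convention, see [cadence()].
#' @return Object of class `gait_analysis`: `metrics` (named list:
#'   `cadence_spm`, `stride_length_m`, `walking_speed_mps`,
#'   `max_foot_elevation_m`, `stance_ratio`, plus `n_strides`,
#'   `duration_s`, `distance_m` and per-metric `sd_*` dispersion across
#'   strides), `per_stride` (data frame), `segmentation`, `zupt`
#'   (the [zupt_correct()] result), `forward` (unit vector), `trace`.
#' @export
analyze_trace <- function(trace, Wd = 15, Td = 3, flat_ground = TRUE,
                          steps_per_stride = 2) {
  calibration <- suppressWarnings(calibrate_trace(trace))
  mask <- detect_stance(trace, Wd = Wd, Td = Td, calibration = calibration)
  z <- zupt_correct(trace, mask = mask, calibration = calibration,
                    flat_ground = flat_ground)
  seg <- segment_gait(mask, trace$dt)
  acc <- which(seg$stance$accepted & !seg$stance$boundary)
  if (length(acc) < 2) {
    stop("not a walking trial: fewer than two accepted stance phases")
  }
  p <- as.matrix(z$nav[, c("px", "py", "pz")])
  stance_pos <- t(vapply(acc, function(j) {
    idx <- seg$stance$start[j]:(seg$stance$end[j] - 1L)
    colMeans(p[idx, , drop = FALSE])
  }, numeric(3)))
  disp <- stance_pos[nrow(stance_pos), ] - stance_pos[1, ]
  disp[3] <- 0
  if (sqrt(sum(disp^2)) < 1e-6) {
    stop("no net horizontal displacement: cannot define a forward direction")
  }
  forward <- disp / sqrt(sum(disp^2))
  p_fwd <- as.numeric(stance_pos %*% forward)
  td_t <- trace$t[seg$stance$start[acc]]
  n_str <- length(acc) - 1L
  T_walk <- td_t[length(td_t)] - td_t[1]

  strides <- seg$strides
  stride_len <- diff(p_fwd)
  elev <- vapply(seq_len(nrow(strides)), function(i) {
    idx <- strides$stance_start[i]:(strides$next_start[i] - 1L)
    base <- mean(p[strides$stance_start[i]:(strides$stance_end[i] - 1L), 3])
    max(p[idx, 3] - base)
  }, numeric(1))
  per_stride <- cbind(strides,
                      stride_length = stride_len[seq_len(nrow(strides))],
                      elevation = elev)
  metrics <- list(
    cadence_spm = cadence(n_str, T_walk, steps_per_stride),
    stride_length_m = stride_length(p_fwd),
    walking_speed_mps = gait_speed(p_fwd[1], p_fwd[length(p_fwd)], T_walk),
    max_foot_elevation_m = mean(elev),
    stance_ratio = mean(strides$stance_ratio),
    n_strides = n_str,
    duration_s = T_walk,
    distance_m = p_fwd[length(p_fwd)] - p_fwd[1],
    sd_stride_length_m = stats::sd(stride_len),
    sd_stance_ratio = stats::sd(strides$stance_ratio),
    sd_max_foot_elevation_m = stats::sd(elev))
  structure(list(metrics = metrics, per_stride = per_stride,
                 segmentation = seg, zupt = z, forward = forward,
                 calibration = calibration, trace = trace),
            class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0(
    "<gait_analysis> %d strides over %.1f s (%.2f m)\n",
    "  cadence %.1f steps/min | stride %.3f m | speed %.3f m/s\n",
    "  stance ratio %.3f | max foot elevation %.3f m\n"),
    m$n_strides, m$duration_s, m$distance_m, m$cadence_spm,
    m$stride_length_m, m$walking_speed_mps, m$stance_ratio,
    m$max_foot_elevation_m))
  invisible(x)
}

#' Sub-phase partition of every accepted stride
#'
#' Applies [partition_subphases()] to the sagittal gyro of each accepted
#' stride's stance interval.
#'
#' @param analysis a [analyze_trace()] result.
#' @param axis sagittal (mediolateral) body axis index, default 2.
#' @return List of data frames, one per accepted stride.
#' @export
stance_subphases <- function(analysis, axis = 2) {
  seg <- analysis$segmentation
  trace <- analysis$trace
  bias <- analysis$calibration$gyro_bias[axis]
  strides <- seg$strides
  lapply(seq_len(nrow(strides)), function(i) {
    idx <- strides$stance_start[i]:(strides$stance_end[i] - 1L)
    partition_subphases(trace$gyro[idx, axis] - bias, trace$dt,
                        start = strides$stance_start[i])
  })
}

#' Complete gait assessment for one or two instrumented limbs
#'
#' Convenience front end: analyses each foot trace, estimates the ankle ROM
#' when a synchronized shank trace is available, computes bilateral symmetry
#' when both feet are present, and assembles a [gait_report()].
#'
#' @param left foot [imu_trace()] (required).
#' @param right optional contralateral foot trace.
#' @param left_shank,right_shank optional synchronized shank traces.
#' @param affected `"left"` or `"right"`: limb reported and used as `Xa` in
#'   the symmetry index.
#' @param reference reference ranges for the report.
#' @param Wd,Td stance-detector parameters.
#' @return Object of class `gait_assessment`: `limbs` (per-side
#'   `gait_analysis`), `metrics_set` ([compute_all()] result), `ankle_rom`
#'   (per-side [ankle_rom()] results), `report` (`NULL` unless the full
#'   seven-metric schema could be populated, i.e. bilateral with a shank on
#'   the affected side).
#' @export
analyze_gait <- function(left, right = NULL, left_shank = NULL,
                         right_shank = NULL, affected = "left",
                         reference = default_reference_ranges(),
                         Wd = 15, Td = 3) {
  limbs <- list(left = analyze_trace(left, Wd = Wd, Td = Td))
  if (!is.null(right)) limbs$right <- analyze_trace(right, Wd = Wd, Td = Td)
  rom <- list()
  if (!is.null(left_shank)) {
    rom$left <- ankle_rom_from_traces(left_shank, left)
  }
  if (!is.null(right_shank) && !is.null(right)) {
    rom$right <- ankle_rom_from_traces(right_shank, right)
  }
  ms <- compute_all(limbs$left, limbs$right, affected = affected,
                    symmetry = !is.null(right))
  report <- NULL
  side <- if (affected %in% names(limbs)) affected else "left"
  m <- limbs[[side]]$metrics
  if (!is.null(rom[[side]]) && !is.null(ms$symmetry)) {
    report <- gait_report(
      c(m[c("cadence_spm", "stride_length_m", "walking_speed_mps",
            "max_foot_elevation_m", "stance_ratio")],
        list(ankle_rom_deg = rom[[side]]$rom_deg,
             gait_symmetry_stance = ms$symmetry$GS[["stance_ratio"]])),
      reference = reference,
      meta = list(duration_s = m$duration_s, stride_count = m$n_strides,
                  distance_m = m$distance_m, affected = affected))
  }
  structure(list(limbs = limbs, metrics_set = ms, ankle_rom = rom,
                 report = report),
            class = "gait_assessment")
}
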