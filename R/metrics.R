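#' Cadence in steps per minute
#'
#' Cadence is the number of walking steps per minute. A single instrumented
#' foot observes strides; for reporting on the conventional two-feet scale
#' each stride counts as `steps_per_stride` steps (default 2), so ~1.07 s
#' strides give the familiar ~112 steps/min of healthy adults.
#'
#' @param n_strides number of strides of the instrumented foot.
#' @param duration_s walking duration in seconds, > 0.
#' @param steps_per_stride steps counted per stride (default 2).
#' @return Cadence, steps/min.
#' @export
cadence <- function(n_strides, duration_s, steps_per_stride = 2) {
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0) {
    stop("duration_s must be a positive scalar")
  }
  60 * steps_per_stride * n_strides / duration_s
}

#' Mean stride length from touchdown positions
#'
#' The mean forward distance between successive touchdowns of the same foot.
#' The mean of successive differences telescopes to `(p_n - p_0) / n`.
#'
#' @param touchdowns forward touchdown positions (m), in time order (>= 2).
#' @return Mean stride length, m.
#' @export
stride_length <- function(touchdowns) {
  p <- as.numeric(touchdowns)
  if (length(p) < 2) stop("need at least 2 touchdown positions")
  mean(diff(p))
}

#' Gait speed
#'
#' Net forward displacement of the foot divided by the walking duration.
#'
#' @param p0,pn first and last forward positions (m).
#' @param duration_s walking duration (s), > 0.
#' @return Speed, m/s.
#' @export
gait_speed <- function(p0, pn, duration_s) {
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0) {
    stop("duration_s must be a positive scalar")
  }
  (pn - p0) / duration_s
}

#' Maximum foot elevation
#'
#' Per-stride maximum of the upward (baseline-corrected) foot position,
#' reported as the trial mean. The input must already be referenced so that
#' the stance-phase height of each stride is zero; the result is then
#' non-negative.
#'
#' @param p_upward upward position sequence (m), baseline-corrected.
#' @param strides optional data frame with `stance_start` and `next_start`
#'   sample indices delimiting each stride; when omitted the global maximum
#'   is returned.
#' @return Max foot elevation, m.
#' @export
max_foot_elevation <- function(p_upward, strides = NULL) {
  z <- as.numeric(p_upward)
  if (is.null(strides) || nrow(strides) == 0) return(max(z))
  mean(vapply(seq_len(nrow(strides)), function(i) {
    idx <- strides$stance_start[i]:(strides$next_start[i] - 1L)
    max(z[idx])
  }, numeric(1)))
}

#' Ankle range of motion from shank and instep angular rates
#'
#' The ankle angle is the integral of the sagittal angular-rate difference
#' between shank and instep, plus the difference of their initial
#' inclinations: `alpha(t) = int(w_shank - w_instep) dt + theta0_shank -
#' theta0_instep`. The range of motion is `max(alpha) - min(alpha)` over the
#' trial, in degrees; the additive initial-angle constant does not affect it.
#'
#' @param w_shank,w_instep sagittal angular-rate sequences (rad/s), equal
#'   length, common time base.
#' @param dt sample interval (s).
#' @param theta0_shank,theta0_instep initial angles versus gravity (rad);
#'   only shift `alpha(t)`, not the ROM.
#' @return List of class `ankle_rom`: `rom_deg`, `alpha` (rad, per sample).
#' @export
ankle_rom <- function(w_shank, w_instep, dt,
                      theta0_shank = 0, theta0_instep = 0) {
  if (length(w_shank) != length(w_instep)) {
    stop("shank and instep sequences must have the same length")
  }
  alpha <- cumtrapz_vec(w_shank - w_instep, dt,
                        theta0_shank - theta0_instep)
  structure(list(rom_deg = (max(alpha) - min(alpha)) * 180 / pi,
                 alpha = alpha),
            class = "ankle_rom")
}

#' Ankle range of motion from a shank/instep trace pair
#'
#' Convenience wrapper: calibrates both traces at standstill (gyro de-bias),
#' extracts the sagittal axis, and runs [ankle_rom()]. Initial inclinations
#' are taken from accelerometer levelling pitch; they cancel in the ROM.
#'
#' @param shank,instep synchronized [imu_trace()]s of the same limb.
#' @param axis sagittal (mediolateral) body axis index, default 2 (y).
#' @return An [ankle_rom()] result.
#' @export
ankle_rom_from_traces <- function(shank, instep, axis = 2) {
  if (length(shank$t) != length(instep$t)) {
    stop("shank and instep traces must have the same length")
  }
  cal_s <- suppressWarnings(calibrate_trace(shank))
  cal_i <- suppressWarnings(calibrate_trace(instep))
  ankle_rom(shank$gyro[, axis] - cal_s$gyro_bias[axis],
            instep$gyro[, axis] - cal_i$gyro_bias[axis],
            shank$dt,
            theta0_shank = levelling_pitch(cal_s$q0),
            theta0_instep = levelling_pitch(cal_i$q0))
}

# pitch of the levelled initial attitude (rotation about the y axis)
levelling_pitch <- function(q) {
  R <- quat_to_matrix(q)
  asin(max(-1, min(1, -R[3, 1])))
}

#' Stance ratio
#'
#' Fraction of the gait cycle spent in stance, `t_stance / (t_stance +
#' t_swing)`; ~0.62 in healthy level walking and close to 0.5 when jogging.
#'
#' @param t_stance,t_swing phase durations (s), both > 0.
#' @return Ratio in (0, 1).
#' @export
stance_ratio <- function(t_stance, t_swing) {
  if (any(t_stance <= 0) || any(t_swing <= 0)) {
    stop("phase durations must be positive")
  }
  t_stance / (t_stance + t_swing)
}

#' Bilateral gait symmetry index
#'
#' `GS = 1 - 2 |Xa - Xs| / (Xa + Xs)` comparing a gait parameter between the
#' affected (`Xa`) and sound (`Xs`) limbs. GS equals 1 for perfect symmetry
#' and decreases as the sides diverge; it is scale-invariant. The
#' absolute-difference convention keeps GS <= 1 regardless of which side is
#' labelled affected; set `signed = TRUE` for the raw signed variant
#' `1 - 2 (Xa - Xs) / (Xa + Xs)`, which can exceed 1 when `Xa < Xs`.
#'
#' @param Xa,Xs parameter values for affected and sound limbs; `Xa + Xs`
#'   must be positive.
#' @param signed use the signed difference instead of its absolute value.
#' @return Symmetry index (dimensionless).
#' @export
gait_symmetry <- function(Xa, Xs, signed = FALSE) {
  if (any(Xa + Xs <= 0)) stop("Xa + Xs must be positive")
  d <- if (signed) (Xa - Xs) else abs(Xa - Xs)
  1 - 2 * d / (Xa + Xs)
}

#' All gait metrics for one or two processed limbs
#'
#' Aggregates the per-limb spatio-temporal parameters from corrected
#' trajectories and segmentations (see [analyze_trace()]) and, when both
#' limbs are present, the symmetry index of every shared parameter with the
#' affected side designated by `affected`.
#'
#' @param left a `gait_analysis` from [analyze_trace()].
#' @param right optional second `gait_analysis` for the other foot.
#' @param affected `"left"` or `"right"`; which limb is the affected one for
#'   symmetry (ignored unilaterally).
#' @param symmetry request the symmetry report; an error if only one limb
#'   was supplied.
#' @return List of class `gait_metrics_set`: `per_limb` (named list of
#'   metric lists), `symmetry` (`NULL` or named GS vector plus the inputs).
#' @export
compute_all <- function(left, right = NULL, affected = "left",
                        symmetry = !is.null(right)) {
  if (symmetry && is.null(right)) {
    stop("symmetry requires traces from both limbs")
  }
  per_limb <- list(left = left$metrics)
  if (!is.null(right)) per_limb$right <- right$metrics
  sym <- NULL
  if (symmetry) {
    affected <- match.arg(affected, c("left", "right"))
    sound <- setdiff(c("left", "right"), affected)
    Xa <- per_limb[[affected]]
    Xs <- per_limb[[sound]]
    keys <- c("cadence_spm", "stride_length_m", "walking_speed_mps",
              "max_foot_elevation_m", "stance_ratio")
    gs <- vapply(keys, function(k) gait_symmetry(Xa[[k]], Xs[[k]]),
                 numeric(1))
    sym <- list(GS = gs, affected = affected,
                Xa = unlist(Xa[keys]), Xs = unlist(Xs[keys]))
  }
  structure(list(per_limb = per_limb, symmetry = sym),
            class = "gait_metrics_set")
}
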