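#' Gait template for the walking-trial simulator
#'
#' The template fixes the commanded per-stride kinematics. The `healthy`
#' preset uses the reference values of healthy adult level walking: stride
#' length 1.19 m, stance fraction 0.62, foot clearance 0.24 m, ankle ROM
#' 70 deg, and a stride time of 60/56 s so that the two-feet cadence is
#' 112 steps/min. The `stroke` preset uses hemiplegic-gait reference means
#' (stride 0.87 m, cadence 85, stance fraction 0.73, clearance 0.13 m, ROM
#' 52 deg) plus asymmetry factors applied to the affected side's stance
#' time, clearance and ROM; stride length and stride time are shared between
#' feet, as they must be in steady gait.
#'
#' @param preset `"healthy"` or `"stroke"`.
#' @param stride_length m. @param stride_time s. @param stance_fraction
#'   in (0,1). @param foot_clearance m. @param ankle_rom degrees.
#' @param asymmetry named list of multiplicative factors for the affected
#'   side: `stance_time`, `clearance`, `rom` (1 = symmetric).
#' @return Object of class `gait_template`.
#' @export
gait_template <- function(preset = c("healthy", "stroke"),
                          stride_length = NULL, stride_time = NULL,
                          stance_fraction = NULL, foot_clearance = NULL,
                          ankle_rom = NULL, asymmetry = NULL) {
  preset <- match.arg(preset)
  def <- if (preset == "healthy") {
    list(stride_length = 1.19, stride_time = 60 / 56,
         stance_fraction = 0.62, foot_clearance = 0.24, ankle_rom = 70,
         asymmetry = list(stance_time = 1, clearance = 1, rom = 1))
  } else {
    # affected-side factors < 1: hemiplegic gait shortens the affected
    # limb's stance and flattens its swing (the sound side compensates
    # with prolonged double support)
    list(stride_length = 0.87, stride_time = 120 / 85,
         stance_fraction = 0.73, foot_clearance = 0.13, ankle_rom = 52,
         asymmetry = list(stance_time = 0.85, clearance = 0.6, rom = 0.75))
  }
  tpl <- list(
    preset = preset,
    stride_length = stride_length %||% def$stride_length,
    stride_time = stride_time %||% def$stride_time,
    stance_fraction = stance_fraction %||% def$stance_fraction,
    foot_clearance = foot_clearance %||% def$foot_clearance,
    ankle_rom = ankle_rom %||% def$ankle_rom,
    asymmetry = utils::modifyList(def$asymmetry, asymmetry %||% list()))
  stopifnot(tpl$stride_length > 0, tpl$stride_time > 0,
            tpl$stance_fraction > 0, tpl$stance_fraction < 1,
            tpl$foot_clearance > 0, tpl$ankle_rom > 0)
  structure(tpl, class = "gait_template")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quintic smoothstep (zero velocity and acceleration at both ends)
s5 <- function(x) x^3 * (10 - 15 * x + 6 * x^2)
ds5 <- function(x) 30 * x^2 - 60 * x^3 + 30 * x^4
d2s5 <- function(x) 60 * x - 180 * x^2 + 120 * x^3
# C2 bump, unit peak at x = 0.5, zero value/slope/curvature at both ends
bump <- function(x) 64 * (x^3 - 3 * x^4 + 3 * x^5 - x^6)
dbump <- function(x) 64 * (3 * x^2 - 12 * x^3 + 15 * x^4 - 6 * x^5)
d2bump <- function(x) 64 * (6 * x - 36 * x^2 + 60 * x^3 - 30 * x^4)
# tilted smooth-trapezoid pulse on [0,1]: quintic rise over [0,q], linear
# decay from 1 to gam over [q, 1-q2], quintic fall gam -> 0 over [1-q2, 1]
tilted_pulse <- function(x, q = 0.15, q2 = 0.25, gam = 0.55) {
  ifelse(x < 0 | x > 1, 0,
         ifelse(x < q, s5(x / q),
                ifelse(x <= 1 - q2,
                       1 + (gam - 1) * (x - q) / (1 - q - q2),
                       gam * s5((1 - x) / q2))))
}

# Vertical clearance arc of the swing, symmetric about mid-swing. The
# vertical acceleration is an envelope-hugging tilted-plateau pulse over the
# first fifth of the swing (lift-off), a broad downward lobe through the
# apex, and the mirrored braking pulse before heel strike. This shape keeps
# the vertical acceleration small where the minimum-jerk forward
# acceleration peaks, so the combined specific force of the healthy preset
# stays inside the sensor's +/-50 m/s^2 dynamic range (peak ~49 m/s^2).
# Evaluated by fine-grid quadrature (closed forms exist but add nothing);
# value, slope and curvature are mutually consistent to ~1e-8.
clearance_profile <- function(s, H, w1 = 0.2) {
  sg <- seq(0, 1, length.out = 40001)
  sm <- pmin(sg, 1 - sg)
  up <- tilted_pulse(sm / w1)
  dn <- bump(pmax(0, pmin(1, (sm - w1) / (1 - 2 * w1))))
  h <- sg[2] - sg[1]
  cum <- function(x) c(0, cumsum((x[-1] + x[-length(x)]) / 2 * h))
  i_mid <- (length(sg) + 1L) %/% 2L
  a <- cum(dn)[i_mid] / cum(up)[i_mid] # zero vertical velocity at apex
  zdd <- a * up - dn
  zd <- cum(zdd)
  z <- cum(zd)
  sc <- H / z[i_mid] # apex height = commanded clearance
  list(z = stats::approx(sg, z * sc, s, rule = 2)$y,
       zd = stats::approx(sg, zd * sc, s, rule = 2)$y,
       zdd = stats::approx(sg, zdd * sc, s, rule = 2)$y)
}

# fixed stance sub-phase geometry of the simulated foot: fractions of the
# stance spent in the loading and pushing rotations and their pitch
# amplitudes (rad). The amplitudes are deliberately tiny: large enough for
# the sagittal-gyro sub-phase peaks to stand clear of sensor noise, small
# enough that the foot remains a zero-velocity target throughout stance.
SIM_W_LOAD <- 0.15
SIM_W_PUSH <- 0.20
SIM_TH_HS <- 0.1 * pi / 180
SIM_TH_TO <- 0.1 * pi / 180
SIM_TH_SWING <- 20 * pi / 180

#' Ground-truth trajectory of one instrumented foot
#'
#' Builds the continuous-time kinematics of one foot over `n_strides`
#' strides of level walking, sampled at `fs`: the foot is fixed during
#' stance (with tiny heel-strike and toe-off pitch rotations), advances by
#' one stride length during swing along a minimum-jerk (quintic) forward
#' profile with a C2 clearance arc, and carries a sagittal pitch profile.
#' The trial starts and ends with a standstill (`lead_s`, `tail_s`) as a
#' wearer would. The ankle-angle profile (shank minus instep inclination)
#' spans the template ROM once per stride.
#'
#' @param template a [gait_template()].
#' @param n_strides number of strides (>= 1).
#' @param fs sample rate, Hz.
#' @param lead_s,tail_s standstill before and after the walk, s.
#' @param side `"left"` or `"right"`; the right foot starts half a stride
#'   later and walks on a parallel line offset laterally.
#' @param affected apply the template's asymmetry factors to this foot.
#' @return Object of class `gait_truth`: `t`, `pos`, `vel`, `acc` (n x 3,
#'   navigation frame, gravity-free), `theta`, `theta_dot` (foot sagittal
#'   pitch, rad and rad/s), `alpha`, `alpha_dot` (ankle angle profile),
#'   `quat` (n x 4 attitude), `stance` (logical), `events` (touchdown and
#'   toe-off times, s), `metrics` (true metric values measured from this
#'   trajectory), `template`, `fs`, `side`.
#' @export
generate_trajectory <- function(template, n_strides, fs = 100,
                                lead_s = 2, tail_s = 2,
                                side = "left", affected = FALSE) {
  st <- template$stride_time
  if (st * fs < 10) stop("infeasible template: fewer than 10 samples per stride")
  fst <- template$stance_fraction
  L <- template$stride_length
  H <- template$foot_clearance
  rom <- template$ankle_rom * pi / 180
  if (affected) {
    fst <- min(0.95, max(0.3, fst * template$asymmetry$stance_time))
    H <- H * template$asymmetry$clearance
    rom <- rom * template$asymmetry$rom
  }
  lead <- if (side == "right") lead_s + st / 2 else lead_s
  tail <- if (side == "right") max(0.5, tail_s - st / 2) else tail_s
  y_off <- if (side == "right") -0.12 else 0.12
  total <- lead + n_strides * st + tail
  n <- floor(total * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  Tsw <- (1 - fst) * st
  Tst <- fst * st

  pos <- matrix(0, n, 3)
  vel <- matrix(0, n, 3)
  acc <- matrix(0, n, 3)
  theta <- numeric(n)
  theta_dot <- numeric(n)
  stance <- rep(TRUE, n)
  pos[, 2] <- y_off

  walking <- t >= lead & t < lead + n_strides * st
  tw <- t[walking] - lead
  stride_i <- pmin(floor(tw / st), n_strides - 1)
  u <- tw / st - stride_i
  in_swing <- u >= fst
  s <- (u - fst) / (1 - fst)

  x <- stride_i * L
  z <- numeric(length(tw))
  vx <- vz <- ax <- az <- numeric(length(tw))
  x[in_swing] <- x[in_swing] + L * s5(s[in_swing])
  arc <- clearance_profile(s[in_swing], H)
  z[in_swing] <- arc$z
  vx[in_swing] <- L * ds5(s[in_swing]) / Tsw
  vz[in_swing] <- arc$zd / Tsw
  ax[in_swing] <- L * d2s5(s[in_swing]) / Tsw^2
  az[in_swing] <- arc$zdd / Tsw^2

  th <- numeric(length(tw))
  thd <- numeric(length(tw))
  uu <- u / fst # fraction of stance
  in_load <- !in_swing & uu < SIM_W_LOAD
  in_push <- !in_swing & uu >= 1 - SIM_W_PUSH
  xl <- uu[in_load] / SIM_W_LOAD
  th[in_load] <- SIM_TH_HS * (1 - s5(xl))
  thd[in_load] <- -SIM_TH_HS * ds5(xl) / (SIM_W_LOAD * Tst)
  xp <- (uu[in_push] - (1 - SIM_W_PUSH)) / SIM_W_PUSH
  th[in_push] <- -SIM_TH_TO * s5(xp)
  thd[in_push] <- -SIM_TH_TO * ds5(xp) / (SIM_W_PUSH * Tst)
  ssw <- s[in_swing]
  th[in_swing] <- -SIM_TH_TO + (SIM_TH_TO + SIM_TH_HS) * s5(ssw) +
    SIM_TH_SWING * bump(ssw)
  thd[in_swing] <- ((SIM_TH_TO + SIM_TH_HS) * ds5(ssw) +
                      SIM_TH_SWING * dbump(ssw)) / Tsw

  pos[walking, 1] <- x
  pos[walking, 3] <- z
  vel[walking, 1] <- vx
  vel[walking, 3] <- vz
  acc[walking, 1] <- ax
  acc[walking, 3] <- az
  theta[walking] <- th
  theta_dot[walking] <- thd
  stance[walking] <- !in_swing

  # before the walk the foot stands at the heel-strike pitch; afterwards it
  # settles flat through one more loading rotation
  theta[t < lead] <- SIM_TH_HS
  after <- t >= lead + n_strides * st
  pos[after, 1] <- n_strides * L
  ta <- (t[after] - (lead + n_strides * st)) / (SIM_W_LOAD * Tst)
  sel <- ta < 1
  theta[after][sel] <- SIM_TH_HS * (1 - s5(ta[sel]))
  theta_dot[after][sel] <- -SIM_TH_HS * ds5(ta[sel]) / (SIM_W_LOAD * Tst)

  # ankle angle: one full cycle per stride, range = rom, quiescent at rest
  prog <- pmin(pmax((t - lead) / st, 0), n_strides)
  alpha <- -(rom / 2) * cos(2 * pi * prog)
  alpha_dot <- (rom / 2) * (2 * pi / st) * sin(2 * pi * prog) *
    (t >= lead & t <= lead + n_strides * st)

  quat <- t(vapply(theta, function(a) quat_from_axis_angle(c(0, 1, 0), a),
                   numeric(4)))

  touchdown_t <- lead + (0:n_strides) * st
  toeoff_t <- lead + (0:(n_strides - 1)) * st + Tst
  events <- list(touchdown_t = touchdown_t, toeoff_t = toeoff_t,
                 touchdown_idx = pmin(n, round(touchdown_t * fs) + 1L))

  # true metric values as measured on this (sampled) trajectory
  td_x <- (0:n_strides) * L
  clearance_sampled <- mean(vapply(seq_len(n_strides), function(i) {
    idx <- which(t >= touchdown_t[i] & t < touchdown_t[i + 1])
    max(pos[idx, 3])
  }, numeric(1)))
  metrics <- list(
    cadence_spm = 120 / st,
    stride_length_m = mean(diff(td_x)),
    walking_speed_mps = (td_x[n_strides + 1] - td_x[1]) / (n_strides * st),
    max_foot_elevation_m = clearance_sampled,
    ankle_rom_deg = (max(alpha) - min(alpha)) * 180 / pi,
    stance_ratio = fst,
    t_stance = Tst, t_swing = Tsw)

  structure(list(t = t, pos = pos, vel = vel, acc = acc,
                 theta = theta, theta_dot = theta_dot,
                 alpha = alpha, alpha_dot = alpha_dot,
                 quat = quat, stance = stance, events = events,
                 metrics = metrics, template = template, fs = fs,
                 side = side, affected = affected,
                 lead_s = lead, tail_s = tail),
            class = "gait_truth")
}

#' Ideal IMU streams from a ground-truth trajectory (inverse strapdown)
#'
#' Solves the strapdown state equations backwards: the body-frame specific
#' force is the rotated sum of the true acceleration and gravity,
#' `a_body = R(q)^T (a_nav + g_n)`, and the body rate follows from the
#' attitude profile (for the sagittal-pitch trajectories generated here,
#' exactly `(0, d(theta)/dt, 0)`). Forward integration of the returned trace
#' by [strapdown_integrate()] reproduces the truth to integration tolerance.
#'
#' @param truth a [generate_trajectory()] result.
#' @param spec a [sensor_spec()].
#' @param placement,node_id trace metadata.
#' @param shank generate the stream of the shank segment instead of the
#'   instep: attitude pitch `theta + alpha`, same translation.
#' @param mag include a magnetometer channel (constant field rotated into
#'   the body frame).
#' @return An ideal (noise-free) [imu_trace()].
#' @export
inverse_strapdown <- function(truth, spec = sensor_spec(),
                              placement = if (shank) "shank" else "instep",
                              node_id = paste0(truth$side, "_", placement),
                              shank = FALSE, mag = FALSE) {
  n <- length(truth$t)
  theta <- if (shank) truth$theta + truth$alpha else truth$theta
  theta_dot <- if (shank) truth$theta_dot + truth$alpha_dot else truth$theta_dot
  f_nav <- truth$acc
  f_nav[, 3] <- f_nav[, 3] + GRAVITY
  # pitch-only attitude: rotate into body frame with R_y(theta)^T
  ct <- cos(theta); stheta <- sin(theta)
  a_body <- cbind(ct * f_nav[, 1] - stheta * f_nav[, 3],
                  f_nav[, 2],
                  stheta * f_nav[, 1] + ct * f_nav[, 3])
  gyro <- cbind(0, theta_dot, 0)
  m <- NULL
  if (mag) {
    m_nav <- c(20, 0, -45)
    m <- cbind(ct * m_nav[1] - stheta * m_nav[3],
               rep(m_nav[2], n),
               stheta * m_nav[1] + ct * m_nav[3])
  }
  imu_trace(truth$t, a_body, gyro, mag = m, node_id = node_id,
            side = truth$side, placement = placement, spec = spec)
}

#' Add sensor noise to an ideal trace
#'
#' Adds a per-trial constant bias drawn per axis with the sensor's bias
#' stability (1 sigma) plus white noise shaped by a Butterworth low-pass at
#' the sensor bandwidth. Bitwise reproducible for a given seed; the global
#' RNG state is left untouched.
#'
#' @param ideal an [imu_trace()].
#' @param spec a [sensor_spec()] providing bias sigmas and bandwidths.
#' @param seed integer seed.
#' @param white_sigma per-sample white-noise sigmas before shaping, named
#'   list: `accel` (m/s^2), `gyro` (deg/s), `mag` (uT).
#' @param scale overall noise scale; 0 returns the input unchanged.
#' @return The noisy [imu_trace()], with the drawn biases in attribute
#'   `bias` (list `accel` m/s^2, `gyro` rad/s, `mag` uT).
#' @export
add_sensor_noise <- function(ideal, spec = sensor_spec(), seed = 1,
                             white_sigma = list(accel = 0.01, gyro = 0.1,
                                                mag = 0.5),
                             scale = 1) {
  if (scale == 0) {
    attr(ideal, "bias") <- list(accel = c(0, 0, 0), gyro = c(0, 0, 0),
                                mag = c(0, 0, 0))
    return(ideal)
  }
  n <- length(ideal$t)
  fs <- ideal$fs
  noise <- with_local_seed(seed, {
    b_a <- stats::rnorm(3, 0, spec$accel_bias_sigma) * scale
    b_g <- stats::rnorm(3, 0, spec$gyro_bias_sigma) * pi / 180 * scale
    b_m <- stats::rnorm(3, 0, spec$mag_bias_sigma) * scale
    w_a <- matrix(stats::rnorm(3 * n, 0, white_sigma$accel), n, 3) * scale
    w_g <- matrix(stats::rnorm(3 * n, 0, white_sigma$gyro), n, 3) *
      pi / 180 * scale
    w_m <- matrix(stats::rnorm(3 * n, 0, white_sigma$mag), n, 3) * scale
    list(b_a = b_a, b_g = b_g, b_m = b_m, w_a = w_a, w_g = w_g, w_m = w_m)
  })
  shape <- function(w, bw) {
    if (2 * bw / fs >= 1) return(w)
    bf <- signal::butter(4, 2 * bw / fs)
    apply(w, 2, function(col) signal::filtfilt(bf, col))
  }
  accel <- ideal$accel + shape(noise$w_a, spec$accel_bandwidth) +
    matrix(noise$b_a, n, 3, byrow = TRUE)
  gyro <- ideal$gyro + shape(noise$w_g, spec$gyro_bandwidth) +
    matrix(noise$b_g, n, 3, byrow = TRUE)
  mag <- NULL
  if (!is.null(ideal$mag)) {
    mag <- ideal$mag + shape(noise$w_m, spec$mag_bandwidth) +
      matrix(noise$b_m, n, 3, byrow = TRUE)
  }
  out <- imu_trace(ideal$t, accel, gyro, mag = mag, node_id = ideal$node_id,
                   side = ideal$side, placement = ideal$placement,
                   spec = spec)
  attr(out, "bias") <- list(accel = noise$b_a, gyro = noise$b_g,
                            mag = noise$b_m)
  out
}

# run code with a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a complete walking trial
#'
#' Generates ground truth and (optionally noisy) IMU traces for one or both
#' feet, optionally with a synchronized shank sensor per foot for ankle-ROM
#' estimation.
#'
#' @param template a [gait_template()].
#' @param n_strides strides per foot.
#' @param seed integer seed driving the sensor noise.
#' @param fs sample rate, Hz.
#' @param noise add Table-style sensor noise.
#' @param bilateral simulate both feet (right foot offset half a stride).
#' @param shank also produce shank traces.
#' @param affected which side carries the template's asymmetry factors.
#' @param spec a [sensor_spec()].
#' @param lead_s,tail_s standstill padding, s.
#' @return List of class `gait_trial`: `traces` (named list: `left`,
#'   optionally `right`, `left_shank`, `right_shank`), `truth` (named list
#'   of [generate_trajectory()] results per side), `template`, `seed`.
#' @export
simulate_trial <- function(template = gait_template(), n_strides = 20,
                           seed = 1, fs = 100, noise = TRUE,
                           bilateral = FALSE, shank = FALSE,
                           affected = "left", spec = sensor_spec(),
                           lead_s = 2, tail_s = 2) {
  sides <- if (bilateral) c("left", "right") else "left"
  truth <- list()
  traces <- list()
  k <- 0L
  for (sd in sides) {
    tr <- generate_trajectory(template, n_strides, fs = fs,
                              lead_s = lead_s, tail_s = tail_s, side = sd,
                              affected = bilateral && sd == affected)
    truth[[sd]] <- tr
    ideal <- inverse_strapdown(tr, spec = spec)
    traces[[sd]] <- if (noise) {
      add_sensor_noise(ideal, spec = spec, seed = seed + k)
    } else ideal
    k <- k + 1L
    if (shank) {
      ideal_s <- inverse_strapdown(tr, spec = spec, shank = TRUE)
      traces[[paste0(sd, "_shank")]] <- if (noise) {
        add_sensor_noise(ideal_s, spec = spec, seed = seed + k)
      } else ideal_s
      k <- k + 1L
    }
  }
  structure(list(traces = traces, truth = truth, template = template,
                 seed = seed),
            class = "gait_trial")
}

#' Simulated scenario for IMU installation-position estimation
#'
#' Builds a rigid limb segment between two joints, an IMU at ratio `k_true`
#' along it, and the consistent inertial streams. In the `rotation` case the
#' segment swings like a pendulum about joint 1 (the installation ratio is
#' observable); in the `translation` case both joints translate together and
#' the IMU displacement equals the joint displacement, leaving `k`
#' unobservable.
#'
#' @param k_true installation ratio in `[0, 1]` (0 = at joint 1).
#' @param motion `"rotation"` or `"translation"`.
#' @param seed integer seed; jitters the motion amplitude and frequency and
#'   drives measurement noise when enabled.
#' @param duration_s motion duration, s.
#' @param lead_s standstill before the motion (s), used for attitude and
#'   gyro-bias calibration when no attitude sequence is supplied.
#' @param fs sample rate, Hz.
#' @param segment_length_m joint-1 to joint-2 distance, m.
#' @param joint_noise_m measurement noise sigma added to the joint
#'   trajectories (0 = noise-free).
#' @return List of class `placement_scenario`: `trace` (ideal
#'   [imu_trace()]), `joints` (data frame `t, p1x..p1z, p2x..p2z`), `quat`
#'   (n x 4 true attitude), `truth` (list with `k_true`, `pos`, `vel`).
#' @export
generate_placement_scenario <- function(k_true,
                                        motion = c("rotation", "translation"),
                                        seed = 1, duration_s = 4,
                                        lead_s = 1.5, fs = 100,
                                        segment_length_m = 0.4,
                                        joint_noise_m = 0) {
  motion <- match.arg(motion)
  if (k_true < 0 || k_true > 1) stop("k_true must be in [0, 1]")
  L <- segment_length_m
  n <- floor((lead_s + duration_s) * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  tm <- pmax(0, t - lead_s) # motion time, zero during the lead standstill
  par <- with_local_seed(seed, {
    list(amp = (25 + stats::runif(1, 0, 10)) * pi / 180,
         freq = 0.4 + stats::runif(1, 0, 0.2))
  })
  if (motion == "rotation") {
    # pendulum about joint 1 at the origin, swing in the sagittal plane;
    # the (1-cos)^2 profile starts from rest with zero acceleration
    w <- 2 * pi * par$freq
    cw <- cos(w * tm); sw <- sin(w * tm)
    phi <- par$amp / 4 * (1 - cw)^2
    phid <- par$amp / 2 * w * (1 - cw) * sw
    phidd <- par$amp / 2 * w^2 * (sw^2 + (1 - cw) * cw)
    p1 <- matrix(0, n, 3)
    p2 <- cbind(-L * sin(phi), 0, -L * cos(phi))
    a2 <- cbind(-L * (phidd * cos(phi) - phid^2 * sin(phi)), 0,
                L * (phidd * sin(phi) + phid^2 * cos(phi)))
    pos <- k_true * p2
    vel <- k_true * cbind(-L * phid * cos(phi), 0, L * phid * sin(phi))
    acc <- k_true * a2
    theta <- phi
    theta_dot <- phid
  } else {
    # rigid translation starting from rest with zero initial acceleration
    amp <- 0.3
    w <- 2 * pi * par$freq
    cw <- cos(w * tm); sw <- sin(w * tm)
    p1 <- cbind(amp / 4 * (1 - cw)^2, 0, 0)
    p2 <- p1 + matrix(c(0, 0, -L), n, 3, byrow = TRUE)
    pos <- p1 + k_true * matrix(c(0, 0, -L), n, 3, byrow = TRUE)
    vel <- cbind(amp / 2 * w * (1 - cw) * sw, 0, 0)
    acc <- cbind(amp / 2 * w^2 * (sw^2 + (1 - cw) * cw), 0, 0)
    theta <- numeric(n)
    theta_dot <- numeric(n)
  }
  ct <- cos(theta); sth <- sin(theta)
  f_nav <- acc
  f_nav[, 3] <- f_nav[, 3] + GRAVITY
  a_body <- cbind(ct * f_nav[, 1] - sth * f_nav[, 3], f_nav[, 2],
                  sth * f_nav[, 1] + ct * f_nav[, 3])
  gyro <- cbind(0, theta_dot, 0)
  quat <- t(vapply(theta, function(a) quat_from_axis_angle(c(0, 1, 0), a),
                   numeric(4)))
  if (joint_noise_m > 0) {
    nz <- with_local_seed(seed + 7L, {
      list(n1 = matrix(stats::rnorm(3 * n, 0, joint_noise_m), n, 3),
           n2 = matrix(stats::rnorm(3 * n, 0, joint_noise_m), n, 3))
    })
    p1 <- p1 + nz$n1
    p2 <- p2 + nz$n2
  }
  trace <- imu_trace(t, a_body, gyro, node_id = "segment",
                     placement = "unknown")
  joints <- data.frame(t = t, p1x = p1[, 1], p1y = p1[, 2], p1z = p1[, 3],
                       p2x = p2[, 1], p2y = p2[, 2], p2z = p2[, 3])
  structure(list(trace = trace, joints = joints, quat = quat,
                 truth = list(k_true = k_true, pos = pos, vel = vel,
                              motion = motion)),
            class = "placement_scenario")
}
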