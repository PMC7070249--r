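#' Adaptive duration filter for candidate gait phases (1-D 2-means)
#'
#' Short spurious stance candidates caused by measurement fluctuation are
#' separated from true phases by clustering candidate durations into two
#' groups. In one dimension the optimal 2-means partition is a split of the
#' sorted durations, so the filter enumerates all splits and takes the one
#' minimising the within-cluster sum of squares — deterministic and exactly
#' the converged k-means solution. The cluster with the larger mean duration
#' is "true"; its extremes become the adaptive time-constraint bounds
#' `[d_min, d_max]`. If the two cluster means are not clearly separated
#' (small mean > `guard` times the large mean) the candidates are considered
#' homogeneous and nothing is rejected.
#'
#' @param durations numeric vector of candidate phase durations (s).
#' @param guard separation guard in (0, 1); default 0.5.
#' @return List of class `duration_filter`: `accepted` (logical per
#'   candidate), `d_min`, `d_max` (bounds from the true cluster), `means`
#'   (false/true cluster means, NA when not split), `filtered` (logical, was
#'   any rejection applied).
#' @export
kmeans_duration_filter <- function(durations, guard = 0.5) {
  d <- as.numeric(durations)
  n <- length(d)
  if (n < 2) {
    warning("fewer than 2 candidates: duration filter passed through")
    return(structure(list(accepted = rep(TRUE, n),
                          d_min = if (n) min(d) else NA_real_,
                          d_max = if (n) max(d) else NA_real_,
                          means = c(low = NA_real_, high = NA_real_),
                          filtered = FALSE),
                     class = "duration_filter"))
  }
  o <- order(d)
  ds <- d[o]
  css <- cumsum(ds)
  css2 <- cumsum(ds^2)
  tot <- css[n]
  tot2 <- css2[n]
  wss <- vapply(seq_len(n - 1), function(m) {
    (css2[m] - css[m]^2 / m) +
      ((tot2 - css2[m]) - (tot - css[m])^2 / (n - m))
  }, numeric(1))
  m <- which.min(wss)
  mu_lo <- css[m] / m
  mu_hi <- (tot - css[m]) / (n - m)
  if (!is.finite(mu_hi) || mu_hi <= 0 || mu_lo > guard * mu_hi) {
    # homogeneous durations: no rejection, bounds span everything
    return(structure(list(accepted = rep(TRUE, n), d_min = min(d),
                          d_max = max(d),
                          means = c(low = NA_real_, high = NA_real_),
                          filtered = FALSE),
                     class = "duration_filter"))
  }
  accepted <- logical(n)
  accepted[o[(m + 1):n]] <- TRUE
  structure(list(accepted = accepted,
                 d_min = ds[m + 1], d_max = ds[n],
                 means = c(low = mu_lo, high = mu_hi), filtered = TRUE),
            class = "duration_filter")
}

#' Segment a stance mask into validated gait cycles
#'
#' Turns the maximal stance runs of a mask into strides. The first and last
#' stance candidates are censored — they merge with lead-in/lead-out
#' standstill or are truncated by the record, so their durations are not
#' comparable — and bypass the duration filter; interior candidates pass
#' through [kmeans_duration_filter()]. A stride spans from one accepted
#' touchdown to the next; its stance phase is the accepted run, its swing
#' phase the remainder.
#'
#' @param mask a [detect_stance()] result (or logical vector).
#' @param dt sample interval (s).
#' @param min_gap_s debounce: stance runs separated by a gap shorter than
#'   this are merged before filtering (no human swing is that short).
#' @return Object of class `gait_segmentation`: `stance` (data frame of
#'   candidates with `start`, `end`, `duration`, `accepted`, `boundary`),
#'   `strides` (data frame `stance_start`, `stance_end`, `next_start`,
#'   `t_stance`, `t_swing`, `stride_time`, `stance_ratio`), `bounds`
#'   (`d_min`, `d_max`), `n_steps` (accepted stance-to-swing transitions),
#'   `dt`.
#' @export
segment_gait <- function(mask, dt, min_gap_s = 0.1) {
  if (inherits(mask, "stance_mask")) {
    mvec <- mask$mask
  } else {
    mvec <- as.logical(mask)
  }
  iv <- stance_intervals(mvec)
  if (nrow(iv) >= 2 && min_gap_s > 0) {
    gaps <- iv$start[-1] - iv$end[-nrow(iv)]
    while (nrow(iv) >= 2 && any(gaps * dt < min_gap_s)) {
      j <- which(gaps * dt < min_gap_s)[1]
      iv$end[j] <- iv$end[j + 1]
      iv <- iv[-(j + 1), , drop = FALSE]
      iv$n <- iv$end - iv$start
      gaps <- if (nrow(iv) >= 2) iv$start[-1] - iv$end[-nrow(iv)] else numeric(0)
    }
    rownames(iv) <- NULL
  }
  n_cand <- nrow(iv)
  bounds <- c(d_min = NA_real_, d_max = NA_real_)
  if (n_cand == 0) {
    seg <- list(stance = cbind(iv, duration = numeric(0),
                               accepted = logical(0), boundary = logical(0)),
                strides = empty_strides(), bounds = bounds, n_steps = 0L,
                dt = dt)
    return(structure(seg, class = "gait_segmentation"))
  }
  iv$duration <- iv$n * dt
  boundary <- seq_len(n_cand) %in% c(1L, n_cand)
  accepted <- rep(TRUE, n_cand)
  interior <- which(!boundary)
  if (length(interior) >= 2) {
    f <- kmeans_duration_filter(iv$duration[interior])
    accepted[interior] <- f$accepted
    bounds <- c(d_min = f$d_min, d_max = f$d_max)
  } else if (length(interior) == 1) {
    bounds <- c(d_min = iv$duration[interior], d_max = iv$duration[interior])
  }
  iv$accepted <- accepted
  iv$boundary <- boundary
  # strides for metric purposes anchor on interior accepted stances only:
  # the censored boundary candidates have no usable touchdown time
  acc <- which(accepted & !boundary)
  strides <- empty_strides()
  if (length(acc) >= 2) {
    a0 <- acc[-length(acc)]
    a1 <- acc[-1]
    strides <- data.frame(
      stance_start = iv$start[a0], stance_end = iv$end[a0],
      next_start = iv$start[a1],
      t_stance = (iv$end[a0] - iv$start[a0]) * dt,
      stride_time = (iv$start[a1] - iv$start[a0]) * dt)
    strides$t_swing <- strides$stride_time - strides$t_stance
    strides$stance_ratio <- strides$t_stance / strides$stride_time
    # a stride needs an actual swing between its two touchdowns
    strides <- strides[strides$t_swing > 0, , drop = FALSE]
    rownames(strides) <- NULL
  }
  # accepted stance -> swing transitions: every accepted run that is followed
  # by at least one non-stance sample
  n_steps <- sum(accepted & iv$end <= length(mvec))
  structure(list(stance = iv, strides = strides, bounds = bounds,
                 n_steps = as.integer(n_steps), dt = dt),
            class = "gait_segmentation")
}

empty_strides <- function() {
  data.frame(stance_start = integer(0), stance_end = integer(0),
             next_start = integer(0), t_stance = numeric(0),
             stride_time = numeric(0), t_swing = numeric(0),
             stance_ratio = numeric(0))
}

#' Count steps with the adaptive detector
#'
#' Runs [detect_stance()] followed by [segment_gait()] and returns the number
#' of accepted stance-to-swing transitions. One step here is one stride of
#' the instrumented foot.
#'
#' @param trace an [imu_trace()].
#' @param Wd,Td detector window (samples) and threshold.
#' @return Integer step count.
#' @export
count_steps <- function(trace, Wd = 15, Td = 3) {
  mask <- detect_stance(trace, Wd = Wd, Td = Td)
  if (!any(mask$mask) || all(mask$mask)) return(0L)
  segment_gait(mask, trace$dt)$n_steps
}

#' Partition a stance interval into loading, foot-flat and pushing
#'
#' Uses the sagittal (mediolateral-axis) angular rate inside the stance:
#' the loading sub-phase runs from stance start to the first zero-crossing
#' after the heel-strike peak, the pushing sub-phase from the last
#' zero-crossing before the toe-off peak to stance end, and foot-flat is the
#' remainder. The three sub-phases tile the stance exactly. If no usable
#' peaks or interior zero-crossings exist (near-constant gyro), the stance is
#' returned unpartitioned with a warning.
#'
#' @param gyro_sag sagittal angular-rate samples (rad/s) covering the stance
#'   interval only.
#' @param dt sample interval (s).
#' @param start first sample index of the stance in the parent trace
#'   (for reporting; default 1).
#' @return Data frame with columns `kind` (`loading`, `foot_flat`,
#'   `pushing` — or a single `stance` row when unpartitioned), `start`,
#'   `end` (half-open sample indices), `duration` (s).
#' @export
partition_subphases <- function(gyro_sag, dt, start = 1L) {
  g <- as.numeric(gyro_sag)
  m <- length(g)
  whole <- data.frame(kind = "stance", start = start, end = start + m,
                      duration = m * dt)
  if (m < 5) {
    warning("stance too short to partition")
    return(whole)
  }
  head_zone <- seq_len(max(2L, floor(0.4 * m)))
  tail_zone <- seq(m - max(2L, floor(0.4 * m)) + 1L, m)
  hs_peak <- head_zone[which.max(abs(g[head_zone]))]
  to_peak <- tail_zone[which.max(abs(g[tail_zone]))]
  sgn <- sign(g)
  crossings <- which(sgn[-m] * sgn[-1] < 0) # crossing between k and k+1
  load_end <- crossings[crossings >= hs_peak]
  push_start <- crossings[crossings < to_peak]
  if (length(load_end) == 0 || length(push_start) == 0) {
    warning("no interior zero-crossings: stance returned unpartitioned")
    return(whole)
  }
  i_load <- load_end[1] + 1L          # first foot-flat sample (local index)
  i_push <- push_start[length(push_start)] + 1L # first pushing sample
  if (i_push <= i_load) {
    warning("sub-phase boundaries cross: stance returned unpartitioned")
    return(whole)
  }
  data.frame(
    kind = c("loading", "foot_flat", "pushing"),
    start = start + c(0L, i_load - 1L, i_push - 1L),
    end = start + c(i_load - 1L, i_push - 1L, m),
    duration = dt * c(i_load - 1L, i_push - i_load, m - i_push + 1L))
}
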