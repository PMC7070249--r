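#' Read an IMU trace from CSV
#'
#' Expects a comma-separated file with header `t,ax,ay,az,gx,gy,gz` and
#' optional `mx,my,mz` columns, UTF-8, `.` decimal, one file per sensor
#' node. By convention the file carries accelerometer data in m/s^2 and
#' gyroscope data in deg/s; the gyro channel is converted to rad/s
#' internally. Timestamps must be strictly increasing with a uniform step.
#'
#' @param path CSV file path.
#' @param units list declaring on-disk units: `accel` (`"m/s2"` or `"g"`)
#'   and `gyro` (`"deg/s"` or `"rad/s"`).
#' @param node_id,side,placement trace metadata (defaults may also come
#'   from a sidecar config via [read_config()]).
#' @param spec a [sensor_spec()] for range validation.
#' @return An [imu_trace()]; out-of-range samples are flagged with a
#'   warning, non-monotonic timestamps are a hard error.
#' @export
read_trace <- function(path, units = list(accel = "m/s2", gyro = "deg/s"),
                       node_id = NULL, side = "unknown",
                       placement = "unknown", spec = sensor_spec()) {
  df <- utils::read.csv(path, header = TRUE)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have header t,ax,ay,az,gx,gy,gz[,mx,my,mz]")
  }
  accel <- as.matrix(df[, c("ax", "ay", "az")])
  gyro <- as.matrix(df[, c("gx", "gy", "gz")])
  if (identical(units$accel, "g")) accel <- accel * GRAVITY
  if (!identical(units$gyro, "rad/s")) gyro <- gyro * pi / 180
  mag <- NULL
  if (all(c("mx", "my", "mz") %in% names(df))) {
    mag <- as.matrix(df[, c("mx", "my", "mz")])
  }
  imu_trace(df$t, accel, gyro, mag = mag,
            node_id = node_id %||% sub("\\.csv$", "", basename(path)),
            side = side, placement = placement, spec = spec)
}

#' Write an IMU trace to CSV
#'
#' Inverse of [read_trace()]: the gyro channel is written in deg/s (unless
#' `units$gyro` says otherwise), full double precision, so a
#' write-then-read round trip reproduces the trace to better than 1e-9.
#'
#' @param trace an [imu_trace()].
#' @param path output CSV path.
#' @param units on-disk units, as in [read_trace()].
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path,
                        units = list(accel = "m/s2", gyro = "deg/s")) {
  gyro <- trace$gyro
  if (!identical(units$gyro, "rad/s")) gyro <- gyro * 180 / pi
  accel <- trace$accel
  if (identical(units$accel, "g")) accel <- accel / GRAVITY
  df <- data.frame(t = trace$t,
                   ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
                   gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3])
  if (!is.null(trace$mag)) {
    df$mx <- trace$mag[, 1]; df$my <- trace$mag[, 2]; df$mz <- trace$mag[, 3]
  }
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline configuration (JSON or YAML)
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Default clinical reference ranges
#'
#' Normal ranges for the seven reported gait parameters, derived from
#' published healthy-adult group statistics (mean +/- 2 s). They are a
#' visual reference for reading a report, not medical evaluation criteria.
#'
#' @return Named list; per metric `min`, `max` (and `unit`).
#' @export
default_reference_ranges <- function() {
  path <- system.file("extdata", "reference_ranges.json",
                      package = "imugait")
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Assemble a gait report
#'
#' Pairs every metric with its reference range and an in-range flag
#' (`reference_min <= value <= reference_max`). All seven schema metrics
#' must be present: `ankle_rom_deg`, `stride_length_m`, `cadence_spm`,
#' `walking_speed_mps`, `stance_ratio`, `max_foot_elevation_m`,
#' `gait_symmetry_stance`.
#'
#' @param metrics named list/vector with the seven schema keys (per-limb
#'   metrics of the reported limb plus the stance-ratio symmetry).
#' @param reference reference ranges as from [default_reference_ranges()].
#' @param meta optional trial metadata list (duration_s, stride_count,
#'   distance_m, ...).
#' @return Object of class `gait_report`: `metrics` (per metric `value`,
#'   `reference_min`, `reference_max`, `in_range`), `meta`.
#' @export
gait_report <- function(metrics, reference = default_reference_ranges(),
                        meta = list()) {
  keys <- c("ankle_rom_deg", "stride_length_m", "cadence_spm",
            "walking_speed_mps", "stance_ratio", "max_foot_elevation_m",
            "gait_symmetry_stance")
  missing <- setdiff(keys, names(metrics))
  missing <- c(missing,
               keys[vapply(keys, function(k)
                 k %in% names(metrics) &&
                   (is.null(metrics[[k]]) || is.na(metrics[[k]])),
                 logical(1))])
  if (length(missing)) {
    stop("report is missing metrics: ", paste(unique(missing), collapse = ", "))
  }
  recs <- lapply(keys, function(k) {
    ref <- reference[[k]]
    if (is.null(ref) || ref$min >= ref$max) {
      stop("invalid reference range for ", k)
    }
    v <- as.numeric(metrics[[k]])
    list(value = v, reference_min = ref$min, reference_max = ref$max,
         in_range = ref$min <= v && v <= ref$max,
         unit = ref$unit %||% "")
  })
  names(recs) <- keys
  structure(list(metrics = recs, meta = meta), class = "gait_report")
}

#' Write a gait report to JSON or Markdown
#'
#' @param report a [gait_report()].
#' @param path output path.
#' @param format `"json"` (machine-readable, stable keys) or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "markdown")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(metrics = report$metrics, meta = report$meta),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    lines <- c("# Gait report", "",
               "| metric | value | reference | in range |",
               "|---|---|---|---|")
    for (k in names(report$metrics)) {
      m <- report$metrics[[k]]
      lines <- c(lines, sprintf(
        "| %s | %.4g %s | [%.4g, %.4g] | %s |",
        k, m$value, m$unit, m$reference_min, m$reference_max,
        if (m$in_range) "yes" else "NO"))
    }
    if (length(report$meta)) {
      lines <- c(lines, "",
                 sprintf("- %s: %s", names(report$meta),
                         vapply(report$meta, function(v)
                           paste(format(v), collapse = " "), character(1))))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a JSON gait report back
#'
#' @param path a JSON file written by [write_report()].
#' @return A [gait_report()] object.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(metrics = x$metrics, meta = x$meta), class = "gait_report")
}

#' @export
print.gait_report <- function(x, ...) {
  cat("<gait_report>\n")
  for (k in names(x$metrics)) {
    m <- x$metrics[[k]]
    cat(sprintf("  %-22s %8.4g %-6s [%g, %g] %s\n", k, m$value, m$unit,
                m$reference_min, m$reference_max,
                if (m$in_range) "ok" else "OUT OF RANGE"))
  }
  invisible(x)
}

#' Export corrected navigation states to CSV
#'
#' Writes `t,qw,qx,qy,qz,vx,vy,vz,px,py,pz` (and the stance flag when a
#' mask is given), for debugging and plotting the drift-correction effect.
#'
#' @param nav navigation-state data frame from [zupt_correct()] or
#'   [strapdown_integrate()].
#' @param path output CSV path.
#' @param mask optional [detect_stance()] result; adds a `stance` column.
#' @return `path`, invisibly.
#' @export
write_nav_states <- function(nav, path, mask = NULL) {
  df <- nav
  if (!is.null(mask)) df$stance <- as.integer(mask$mask)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
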