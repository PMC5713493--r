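# ImuRecording: the time-stamped body-frame sensor series.

#' Standard gravity, m/s^2
#' @export
STANDARD_GRAVITY <- 9.80665

#' Construct an IMU recording
#'
#' @param t sample times, s, strictly increasing and nominally uniform.
#' @param accel n x 3 specific force in the IMU frame, m/s^2. A stationary,
#'   level sensor reads `c(0, 0, gravity_mag)`.
#' @param gyro n x 3 angular rate in the IMU frame, rad/s.
#' @param fs nominal sampling rate, Hz. Defaults to `1 / median(diff(t))`.
#' @param side `"left"`, `"right"` or `"unknown"`.
#' @param gravity_mag local gravity magnitude G, m/s^2.
#' @param jitter_tol maximum tolerated relative deviation of `diff(t)` from
#'   `1/fs` before a warning is raised.
#' @return Object of class `imu_recording`.
#' @export
imu_recording <- function(t, accel, gyro, fs = NULL,
                          side = c("unknown", "left", "right"),
                          gravity_mag = STANDARD_GRAVITY,
                          jitter_tol = 0.01) {
  side <- match.arg(side)
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  dimnames(accel) <- NULL; dimnames(gyro) <- NULL
  n <- length(t)
  if (n < 2) stop("recording must contain at least 2 samples", call. = FALSE)
  if (nrow(accel) != n || nrow(gyro) != n || ncol(accel) != 3 || ncol(gyro) != 3) {
    stop("accel and gyro must be n x 3 with n == length(t)", call. = FALSE)
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop("time stamps must be strictly increasing (duplicate or reversed time)",
         call. = FALSE)
  }
  if (is.null(fs)) fs <- 1 / stats::median(dt)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (!is.numeric(gravity_mag) || gravity_mag <= 0) {
    stop("gravity_mag must be > 0", call. = FALSE)
  }
  jitter <- max(abs(dt * fs - 1))
  if (jitter > jitter_tol) {
    warning(sprintf(paste0("sample-interval jitter %.2f%% exceeds %.2f%%; ",
                           "consider resample_recording()"),
                    100 * jitter, 100 * jitter_tol), call. = FALSE)
  }
  structure(list(t = as.numeric(t), accel = accel, gyro = gyro, fs = fs,
                 side = side, gravity_mag = gravity_mag),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "IMU recording: %d samples @ %.6g Hz (%.4f s), side %s, G = %.5f m/s^2\n",
    length(x$t), x$fs, x$t[length(x$t)] - x$t[1], x$side, x$gravity_mag))
  invisible(x)
}

#' Duration of a recording, s
#' @param rec an `imu_recording`.
#' @export
recording_duration <- function(rec) rec$t[length(rec$t)] - rec$t[1]

#' Read an IMU recording from CSV
#'
#' The canonical on-disk schema is a plain CSV with columns
#' `t,ax,ay,az,gx,gy,gz` plus an optional JSON sidecar (`<path>.json`)
#' carrying `fs`, `side`, `units` and `gravity_mag`. Unit conversion to SI
#' (m/s^2, rad/s) is applied exactly once, here.
#'
#' @param path CSV file path.
#' @param schema named character vector mapping the canonical names
#'   `t, ax, ay, az, gx, gy, gz` to the file's column names.
#' @param units list with elements `accel` (`"m/s^2"` or `"g"`) and `gyro`
#'   (`"rad/s"` or `"deg/s"`). Overridden by the sidecar if present.
#' @param fs,side,gravity_mag metadata overrides (sidecar wins over defaults,
#'   explicit arguments win over the sidecar).
#' @param resample if `TRUE`, linearly resample onto the uniform nominal grid
#'   when timestamp jitter exceeds 1%.
#' @return An [imu_recording()].
#' @export
read_recording <- function(path,
                           schema = c(t = "t", ax = "ax", ay = "ay", az = "az",
                                      gx = "gx", gy = "gy", gz = "gz"),
                           units = list(accel = "m/s^2", gyro = "rad/s"),
                           fs = NULL, side = NULL, gravity_mag = NULL,
                           resample = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- utils::read.csv(path, check.names = FALSE)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing_cols <- setdiff(need, names(schema))
  if (length(missing_cols)) {
    stop("schema error: no mapping for column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(unname(schema[need]), names(dat))
  if (length(absent)) {
    stop("schema error: column(s) not in file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else list()
  if (!is.null(meta$units)) units <- utils::modifyList(units, as.list(meta$units))
  if (is.null(fs)) fs <- meta$fs
  if (is.null(side)) side <- if (is.null(meta$side)) "unknown" else meta$side
  if (is.null(gravity_mag)) {
    gravity_mag <- if (is.null(meta$gravity_mag)) STANDARD_GRAVITY else meta$gravity_mag
  }
  t <- dat[[schema[["t"]]]]
  accel <- as.matrix(dat[, schema[c("ax", "ay", "az")]])
  gyro <- as.matrix(dat[, schema[c("gx", "gy", "gz")]])
  accel <- accel * accel_unit_factor(units$accel, gravity_mag)
  gyro <- gyro * gyro_unit_factor(units$gyro)
  rec <- imu_recording(t, accel, gyro, fs = fs, side = side,
                       gravity_mag = gravity_mag)
  if (resample) rec <- resample_recording(rec)
  rec
}

#' @keywords internal
accel_unit_factor <- function(unit, gravity_mag = STANDARD_GRAVITY) {
  switch(unit,
         "m/s^2" = 1, "m/s2" = 1, "mps2" = 1,
         "g" = gravity_mag,
         stop("unknown accelerometer unit: ", unit, call. = FALSE))
}

#' @keywords internal
gyro_unit_factor <- function(unit) {
  switch(unit,
         "rad/s" = 1, "rads" = 1,
         "deg/s" = pi / 180, "degs" = pi / 180,
         stop("unknown gyroscope unit: ", unit, call. = FALSE))
}

#' Resample a recording onto its uniform nominal grid
#' @param rec an `imu_recording`.
#' @export
resample_recording <- function(rec) {
  n <- length(rec$t)
  tu <- rec$t[1] + seq(0, by = 1 / rec$fs,
                       length.out = floor((rec$t[n] - rec$t[1]) * rec$fs) + 1)
  interp <- function(m) {
    vapply(seq_len(ncol(m)),
           function(j) stats::approx(rec$t, m[, j], xout = tu)$y,
           numeric(length(tu)))
  }
  imu_recording(tu, interp(rec$accel), interp(rec$gyro), fs = rec$fs,
                side = rec$side, gravity_mag = rec$gravity_mag)
}

#' Write an IMU recording to CSV (+ JSON sidecar)
#'
#' @param rec an `imu_recording`.
#' @param path output CSV path; metadata goes to `<path>.json`.
#' @param sidecar write the JSON sidecar?
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sidecar = TRUE) {
  df <- data.frame(t = rec$t,
                   ax = rec$accel[, 1], ay = rec$accel[, 2], az = rec$accel[, 3],
                   gx = rec$gyro[, 1], gy = rec$gyro[, 2], gz = rec$gyro[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(fs = rec$fs, side = rec$side, gravity_mag = rec$gravity_mag,
           units = list(accel = "m/s^2", gyro = "rad/s")),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# Column order and units of the on-disk stride metrics CSV.
METRICS_COLUMNS <- c("stride_id", "side", "t_strike", "t_off", "t_stride",
                     "t_stance", "t_swing", "t_ps", "clearance_m", "ke_m",
                     "theta_break_deg", "theta_prop_deg", "theta_bounce_deg",
                     "gf_m")

#' Write a stride metrics table to CSV
#'
#' Columns (in order): `stride_id`, `side`, `t_strike` (s), `t_off` (s),
#' `t_stride` (s), `t_stance` (s), `t_swing` (s), `t_ps` (%), `clearance_m`
#' (m), `ke_m` ((m/s)^2), `theta_break_deg`, `theta_prop_deg`,
#' `theta_bounce_deg` (deg), `gf_m` (N/kg). Round-trips losslessly via
#' [read_metrics()] at full double precision.
#'
#' @param table a `stride_metrics` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(table, path) {
  if (is.null(table) || nrow(table) == 0) {
    stop("refusing to write an empty metrics table", call. = FALSE)
  }
  out <- table[, METRICS_COLUMNS]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.12g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stride metrics table written by [write_metrics()]
#' @param path CSV path.
#' @return A `stride_metrics` data.frame.
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  absent <- setdiff(METRICS_COLUMNS, names(df))
  if (length(absent)) {
    stop("metrics file is missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("stride_metrics", "data.frame")
  df
}
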