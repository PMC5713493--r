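# Detection of the stationary periods t_s of the stance phase. These gate the
# orientation measurement updates, the ZUPT, and the elevation corrections.
#
# Detection is two-tiered. Per-sample gates on the gyro magnitude and on the
# deviation of the accelerometer magnitude from gravity must be loose enough
# to tolerate sensor noise; that looseness admits brief windows of slow,
# coordinated motion (the foot "floating" just before contact) that are not
# stance. A genuinely stationary interval, however, has interval-mean
# statistics far below the per-sample gates, so candidate intervals whose
# mean gyro magnitude or mean accelerometer deviation exceeds a configurable
# fraction of the gates are rejected.

#' Detect stationary (stance) periods
#'
#' A sample is stationary iff the gyro magnitude is below
#' `cfg$stance_gyro_thr` AND the accelerometer magnitude deviates from
#' gravity by less than `cfg$stance_accel_thr` (a combined AND rule: the
#' accelerometer alone cannot rule out constant-velocity motion, the gyro
#' alone misses pure translation). The raw mask is then cleaned
#' morphologically: gaps up to `cfg$stance_gap_s` are closed, runs shorter
#' than `cfg$stance_min_s` are dropped. Running stance is brief (roughly
#' 45--55% of ~0.6 s strides), hence the short default minimum duration.
#'
#' @param rec an [imu_recording()].
#' @param cfg a [stairgait_config()].
#' @return Object of class `stationary_mask`: list with `mask` (logical per
#'   sample), `intervals` (half-open `[start, end)` sample-index matrix) and
#'   `t` (the sample times).
#' @export
detect_stationary <- function(rec, cfg = stairgait_config()) {
  gyro_mag <- row_norm(rec$gyro)
  accel_dev <- abs(row_norm(rec$accel) - rec$gravity_mag)
  raw <- gyro_mag < cfg$stance_gyro_thr & accel_dev < cfg$stance_accel_thr
  gap_max <- max(0L, round(cfg$stance_gap_s * rec$fs))
  min_len <- max(1L, round(cfg$stance_min_s * rec$fs))
  mask <- mask_open(mask_close(raw, gap_max), min_len)
  if (any(mask)) {
    iv <- mask_to_intervals(mask)
    keep <- vapply(seq_len(nrow(iv)), function(i) {
      sel <- iv[i, 1]:(iv[i, 2] - 1L)
      mean(gyro_mag[sel]) < cfg$stance_mean_factor * cfg$stance_gyro_thr &&
        mean(accel_dev[sel]) < cfg$stance_mean_factor * cfg$stance_accel_thr
    }, logical(1))
    mask <- intervals_to_mask(iv[keep, , drop = FALSE], length(mask))
  }
  if (!any(mask)) {
    stop(sprintf(paste0(
      "no stationary samples found (min gyro magnitude %.3f rad/s vs ",
      "threshold %.3f; min |accel dev| %.3f m/s^2 vs threshold %.3f)"),
      min(gyro_mag), cfg$stance_gyro_thr,
      min(accel_dev), cfg$stance_accel_thr), call. = FALSE)
  }
  structure(list(mask = mask, intervals = mask_to_intervals(mask), t = rec$t),
            class = "stationary_mask")
}

#' @export
print.stationary_mask <- function(x, ...) {
  cat(sprintf("Stationary mask: %d intervals, %.1f%% of %d samples stationary\n",
              nrow(x$intervals), 100 * mean(x$mask), length(x$mask)))
  invisible(x)
}

#' Temporal midpoints of stationary intervals
#'
#' One anchor time per interval: the mean of the first and last sample time
#' of the interval (for an even-length interval this falls between samples).
#' These anchors tie the ZUPT and elevation corrections to mid-stance, where
#' the foot is most reliably at rest.
#'
#' @param mask a `stationary_mask`.
#' @param t sample times; defaults to the times stored in the mask.
#' @return Numeric vector of anchor times, strictly increasing.
#' @export
interval_midpoints <- function(mask, t = mask$t) {
  iv <- mask$intervals
  if (is.null(iv) || nrow(iv) == 0) stop("mask has no intervals", call. = FALSE)
  (t[iv[, 1]] + t[iv[, 2] - 1L]) / 2
}

#' Export a stationary mask as a debug CSV (`t,is_stationary`)
#' @param mask a `stationary_mask`.
#' @param path output CSV path.
#' @export
write_mask <- function(mask, path) {
  utils::write.csv(data.frame(t = mask$t, is_stationary = mask$mask),
                   path, row.names = FALSE)
  invisible(path)
}
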