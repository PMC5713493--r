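# Strapdown trajectory estimation: rotate the specific force into the
# navigation frame, remove gravity, doubly integrate, de-drift with the ZUPT,
# and correct elevation against the known stair riser ladder.

#' @keywords internal
trajectory_series <- function(t, a_n, v = NULL, p = NULL, stage = "raw",
                              extras = list()) {
  obj <- c(list(t = t, a_n = a_n, v = v, p = p, stage = stage), extras)
  class(obj) <- "trajectory_series"
  obj
}

#' @export
print.trajectory_series <- function(x, ...) {
  cat(sprintf("Trajectory series: %d samples, stage '%s'", length(x$t), x$stage))
  if (!is.null(x$p)) {
    cat(sprintf(", elevation range [%.3f, %.3f] m",
                min(x$p[, 3]), max(x$p[, 3])))
  }
  cat("\n")
  invisible(x)
}

#' Navigation-frame free acceleration
#'
#' Rotates the measured specific force into the navigation frame and removes
#' gravity: \eqn{a_n = R(q)\, a_f - [0, 0, G]} with the z-up navigation
#' frame, so a perfectly oriented stationary sensor yields \eqn{a_n \equiv 0}.
#'
#' @param rec an [imu_recording()].
#' @param orient an `orientation_series` aligned sample-wise with `rec`.
#' @return A `trajectory_series` at stage `"raw"` containing `a_n` only.
#' @export
navigation_acceleration <- function(rec, orient) {
  if (length(orient$t) != length(rec$t)) {
    stop("orientation and recording length mismatch", call. = FALSE)
  }
  a_n <- quat_rotate(orient$q, rec$accel)
  a_n[, 3] <- a_n[, 3] - rec$gravity_mag
  trajectory_series(rec$t, a_n)
}

#' Integrate free acceleration to velocity and position
#'
#' Trapezoidal cumulative integration of
#' \eqn{v = v_0 + \int a_n\,dt}, \eqn{p = p_0 + \int v\,dt}. The run starts
#' from a standstill, so both initial conditions default to zero.
#'
#' @param traj a `trajectory_series` with `a_n` present.
#' @param v0,p0 initial velocity (m/s) and position (m), length-3.
#' @return A `trajectory_series` at stage `"raw"` with `v` and `p` filled.
#' @export
integrate_trajectory <- function(traj, v0 = c(0, 0, 0), p0 = c(0, 0, 0)) {
  if (is.null(traj$a_n)) stop("a_n missing from trajectory", call. = FALSE)
  v <- cumtrapz_cols(traj$t, traj$a_n)
  v <- sweep(v, 2, -v0)
  p <- cumtrapz_cols(traj$t, v)
  p <- sweep(p, 2, -p0)
  trajectory_series(traj$t, traj$a_n, v, p, stage = "raw")
}

#' Zero-velocity update (ZUPT)
#'
#' Any velocity estimated during a stationary period is attributed to
#' accumulated drift. The drift is modelled as piecewise linear in time
#' through the anchor residuals: each stationary interval contributes one
#' anchor at its temporal midpoint carrying the interval-mean raw velocity
#' (robust to one-sample boundary misdetection). The correction ramps
#' linearly from zero at the recording start through each anchor residual and
#' is held constant after the last anchor; subtracting it zeroes the velocity
#' at every anchor and position is re-integrated from the corrected velocity.
#'
#' @param traj a `trajectory_series` at stage `"raw"`.
#' @param mask a `stationary_mask` with at least 2 intervals.
#' @return A `trajectory_series` at stage `"zupt"`; elements `anchors`
#'   (times) and `residuals` (n_anchor x 3) document the corrections.
#' @export
apply_zupt <- function(traj, mask) {
  if (is.null(traj$v)) stop("trajectory must be integrated first", call. = FALSE)
  iv <- mask$intervals
  if (nrow(iv) < 2) {
    stop("ZUPT needs at least 2 stationary intervals to estimate drift",
         call. = FALSE)
  }
  t <- traj$t
  anchors <- interval_midpoints(mask, t)
  resid <- t(vapply(seq_len(nrow(iv)), function(i) {
    colMeans(traj$v[iv[i, 1]:(iv[i, 2] - 1L), , drop = FALSE])
  }, numeric(3)))
  # drift knots: zero at start, residual at each anchor; after the last
  # anchor the drift is extrapolated with the final inter-anchor slope (the
  # drift source persists, it does not stop at the last footfall)
  kt <- c(t[1], anchors)
  kv <- rbind(0, resid)
  if (anchors[1] <= t[1]) { kt <- anchors; kv <- resid }
  nk <- length(kt)
  if (nk >= 2 && t[length(t)] > kt[nk]) {
    slope <- (kv[nk, ] - kv[nk - 1, ]) / (kt[nk] - kt[nk - 1])
    kv <- rbind(kv, kv[nk, ] + slope * (t[length(t)] - kt[nk]))
    kt <- c(kt, t[length(t)])
  }
  drift <- vapply(1:3, function(j) {
    stats::approx(kt, kv[, j], xout = t, rule = 2)$y
  }, numeric(length(t)))
  v <- traj$v - drift
  p <- cumtrapz_cols(t, v)
  p <- sweep(p, 2, -traj$p[1, ])
  trajectory_series(t, traj$a_n, v, p, stage = "zupt",
                    extras = list(anchors = anchors, residuals = resid,
                                  intervals = iv))
}

#' Footfall ladder: tread index and target elevation per stationary interval
#'
#' Assigns to each stationary anchor the tread index
#' \eqn{n = \mathrm{round}(p_z / H)}, clipped so that consecutive footfalls
#' advance by at most one tread in the run direction (the protocol is running
#' without skipping treads; repeated anchors on one tread, e.g. the starting
#' standstill, are allowed). Target elevation is \eqn{H\,n}.
#'
#' @param traj a `trajectory_series` at stage `"zupt"`.
#' @param mask the `stationary_mask` used for the ZUPT.
#' @param geom a [stair_geometry()].
#' @return data.frame of class `footfall_ladder` with columns `time`,
#'   `tread`, `target_m`, `raw_tread`.
#' @export
build_footfall_ladder <- function(traj, mask, geom) {
  if (!identical(traj$stage, "zupt")) {
    stop("footfall ladder requires a ZUPT-corrected trajectory", call. = FALSE)
  }
  H <- geom$riser_m
  anchors <- interval_midpoints(mask, traj$t)
  pz <- stats::approx(traj$t, traj$p[, 3], xout = anchors, rule = 2)$y
  raw <- round(pz / H)
  n <- integer(length(raw))
  n[1] <- raw[1]
  up <- geom$direction == "ascent"
  for (i in seq_along(raw)[-1]) {
    lo <- if (up) n[i - 1] else n[i - 1] - 1L
    hi <- if (up) n[i - 1] + 1L else n[i - 1]
    n[i] <- min(max(raw[i], lo), hi)
  }
  if (any(abs(raw - n) >= 1)) {
    bad <- which(abs(raw - n) >= 1)
    warning(sprintf(paste0(
      "footfall ladder clipped %d anchor(s) by >= 1 tread (first at t=%.2f s,",
      " raw %d -> %d): trajectory badly drifted"),
      length(bad), anchors[bad[1]], raw[bad[1]], n[bad[1]]), call. = FALSE)
  }
  structure(data.frame(time = anchors, tread = n, target_m = H * n,
                       raw_tread = raw),
            class = c("footfall_ladder", "data.frame"))
}

#' Elevation correction against the riser ladder
#'
#' A single-state Kalman filter on the vertical foot position: between
#' footfalls the state uncertainty grows by the per-stride process noise; at
#' each footfall anchor the filter observes the tread elevation \eqn{H\,n}
#' (measurement noise reflecting sub-centimetre stair geometry) and corrects
#' the state. Each correction is distributed backward over the preceding
#' inter-anchor segment by linear interpolation in time, so the corrected
#' trajectory remains continuous, and is carried forward in full after the
#' anchor. Only the z-component of position is modified.
#'
#' @param traj a `trajectory_series` at stage `"zupt"`.
#' @param ladder a `footfall_ladder`.
#' @param cfg a [stairgait_config()] (fields `elev_process_m`,
#'   `elev_meas_m`).
#' @return A `trajectory_series` at stage `"elevation"`; element
#'   `elev_updates` logs innovation, gain and applied correction per
#'   footfall.
#' @export
apply_elevation_filter <- function(traj, ladder, cfg = stairgait_config()) {
  if (!identical(traj$stage, "zupt")) {
    stop("elevation filter requires a ZUPT-corrected trajectory", call. = FALSE)
  }
  t <- traj$t
  pz <- traj$p[, 3]
  qproc <- cfg$elev_process_m^2
  rmeas <- cfg$elev_meas_m^2
  P <- qproc  # one stride of drift uncertainty at the first footfall
  corr <- numeric(length(t))
  log <- vector("list", nrow(ladder))
  prev_time <- t[1]
  for (i in seq_len(nrow(ladder))) {
    ti <- ladder$time[i]
    if (i > 1) P <- P + qproc
    zi <- stats::approx(t, pz + corr, xout = ti, rule = 2)$y
    innov <- ladder$target_m[i] - zi
    K <- P / (P + rmeas)
    ci <- K * innov
    ramp <- ifelse(t <= prev_time, 0,
                   ifelse(t >= ti, 1, (t - prev_time) / (ti - prev_time)))
    corr <- corr + ci * ramp
    P <- (1 - K) * P
    log[[i]] <- data.frame(time = ti, tread = ladder$tread[i], innov = innov,
                           gain = K, correction = ci)
    prev_time <- ti
  }
  p <- traj$p
  p[, 3] <- p[, 3] + corr
  trajectory_series(t, traj$a_n, traj$v, p, stage = "elevation",
                    extras = list(anchors = traj$anchors,
                                  residuals = traj$residuals,
                                  intervals = traj$intervals,
                                  ladder = ladder,
                                  elev_updates = do.call(rbind, log),
                                  z_correction = corr))
}

#' Export a trajectory series to CSV
#'
#' Columns: `t,ax_n,ay_n,az_n,vx,vy,vz,px,py,pz,stage`.
#' @param traj a `trajectory_series` with `v` and `p` present.
#' @param path output CSV path.
#' @export
write_trajectory <- function(traj, path) {
  if (is.null(traj$p)) stop("trajectory has no position yet", call. = FALSE)
  df <- data.frame(t = traj$t,
                   ax_n = traj$a_n[, 1], ay_n = traj$a_n[, 2],
                   az_n = traj$a_n[, 3],
                   vx = traj$v[, 1], vy = traj$v[, 2], vz = traj$v[, 3],
                   px = traj$p[, 1], py = traj$p[, 2], pz = traj$p[, 3],
                   stage = traj$stage)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
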