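# End-to-end pipeline: stance detection -> orientation fusion -> strapdown
# integration -> ZUPT -> elevation correction -> event detection -> metrics.

#' Analyze one stair run recorded by a foot-mounted IMU
#'
#' Runs the full processing chain on one recording and returns every
#' intermediate product along with the per-stride metrics table.
#'
#' @param rec an [imu_recording()].
#' @param geom a [stair_geometry()] (riser height drives the elevation
#'   correction; `direction` selects the extremum rules).
#' @param cfg a [stairgait_config()].
#' @param q0 optional initial orientation quaternion; by default derived
#'   from the pre-run standstill tilt.
#' @return Object of class `stair_run`: list with `mask`, `orientation`,
#'   `trajectory` (stage `"elevation"`), `envelope`, `events` (with stride
#'   times), `metrics` (steady-state strides only), `metrics_all` (including
#'   transition strides), plus the inputs.
#' @export
analyze_stair_run <- function(rec, geom, cfg = stairgait_config(), q0 = NULL) {
  if (isTRUE(cfg$use_nominal_fs)) {
    rec$t <- rec$t[1] + (seq_along(rec$t) - 1) / rec$fs
  }
  mask <- detect_stationary(rec, cfg)
  orient <- fuse_orientation(rec, mask, cfg, q0 = q0)
  traj <- navigation_acceleration(rec, orient)
  traj <- integrate_trajectory(traj)
  traj <- apply_zupt(traj, mask)
  ladder <- build_footfall_ladder(traj, mask, geom)
  traj <- apply_elevation_filter(traj, ladder, cfg)
  envelope <- wavelet_event_signal(rec, cfg)
  events <- detect_events(envelope, mask, cfg, side = rec$side)
  events <- stride_times(events)
  metrics_all <- assemble_metrics(traj, orient, events, geom$direction, cfg,
                                  drop_transition = FALSE)
  metrics <- metrics_all[!metrics_all$is_transition &
                           !is.na(metrics_all$t_stride), , drop = FALSE]
  rownames(metrics) <- NULL
  class(metrics) <- c("stride_metrics", "data.frame")
  structure(list(recording = rec, geometry = geom, config = cfg,
                 mask = mask, orientation = orient, trajectory = traj,
                 ladder = ladder, envelope = envelope, events = events,
                 metrics = metrics, metrics_all = metrics_all),
            class = "stair_run")
}

#' @export
print.stair_run <- function(x, ...) {
  cat(sprintf("Stair run (%s): %d stationary intervals, %d footfalls, %d steady strides\n",
              x$geometry$direction, nrow(x$mask$intervals), nrow(x$events),
              nrow(x$metrics)))
  print(x$metrics)
  invisible(x)
}

#' Plot a stair run: foot elevation and speed with detected events
#'
#' @param x a `stair_run`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stair_run <- function(x, ...) {
  traj <- x$trajectory
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(traj$t, traj$p[, 3], type = "l", xlab = "time (s)",
                 ylab = "foot elevation (m)", ...)
  graphics::abline(h = x$ladder$target_m, col = "grey80", lty = 3)
  graphics::points(x$events$t_strike,
                   traj$p[nearest_index(traj$t, x$events$t_strike), 3],
                   col = "red", pch = 16)
  ok <- !is.na(x$events$t_off)
  graphics::points(x$events$t_off[ok],
                   traj$p[nearest_index(traj$t, x$events$t_off[ok]), 3],
                   col = "darkgreen", pch = 16)
  graphics::plot(traj$t, row_norm(traj$v), type = "l", xlab = "time (s)",
                 ylab = "foot speed (m/s)")
  invisible(x)
}
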