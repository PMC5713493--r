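# Pipeline configuration and stair geometry.

#' Pipeline configuration
#'
#' Collects every tuning constant of the processing pipeline in one validated
#' list. All internal units are SI (m/s^2, rad/s, s, m); angles appear in
#' degrees only at the reporting boundary.
#'
#' @param stance_gyro_thr stationarity threshold on the gyro magnitude
#'   \eqn{\lVert\omega_f\rVert}, rad/s. A sample can only be stationary when
#'   the rate magnitude is below this.
#' @param stance_accel_thr stationarity threshold on the deviation of the
#'   accelerometer magnitude from gravity,
#'   \eqn{|\lVert a_f \rVert - G|}, m/s^2.
#' @param stance_min_s minimum duration of a stationary interval, s. Shorter
#'   runs are dropped (morphological opening).
#' @param stance_gap_s maximum gap bridged inside a stationary interval, s
#'   (morphological closing).
#' @param stance_mean_factor second-tier interval validation: a candidate
#'   stationary interval is kept only if its interval-mean gyro magnitude and
#'   accelerometer deviation are below this fraction of the per-sample
#'   gates. Rejects slow coordinated motion (pre-strike foot float) that
#'   slips under the per-sample thresholds.
#' @param standstill_s stationary intervals at least this long are treated as
#'   standstills separating runs, not in-run footfalls.
#' @param orient_process_deg tilt random-walk intensity of the orientation
#'   Kalman filter, deg/sqrt(s). Deliberately larger than the pure
#'   angle-random-walk of a consumer gyro so the filter also absorbs
#'   uncompensated bias drift between stance updates.
#' @param orient_meas_deg 1-sigma of the accelerometer tilt observation, deg.
#' @param orient_p0_deg initial 1-sigma tilt uncertainty, deg.
#' @param elev_process_m 1-sigma vertical drift of the trajectory per stride,
#'   m (elevation-filter process noise).
#' @param elev_meas_m 1-sigma of the riser-ladder elevation observation, m
#'   (stair geometry is known to sub-centimetre).
#' @param wavelet_floor_hz lower edge of the high-frequency band used for gait
#'   event detection, Hz. Must be below fs/2.
#' @param event_k detection threshold factor: an envelope peak counts as an
#'   event only above `event_k` times the median envelope.
#' @param event_rel_frac when locating the foot-strike, the earliest local
#'   envelope maximum is accepted only if it reaches this fraction of the
#'   window maximum (guards against picking noise ahead of the transient).
#' @param event_window_s half-width of the search window for foot-strike
#'   (before a stationary interval) and toe-off (after it), s.
#' @param env_smooth_s width of the centred moving average applied to the
#'   squared wavelet detail envelope, s.
#' @param n_transition number of footfalls flagged as transition (and
#'   excluded from steady-state metrics) at each end of a run.
#' @param ke_mode `"mean-then-square"` computes the kinetic-energy proxy as
#'   the squared stride-mean foot speed over two (the definition used
#'   throughout); `"mean-of-squares"` is a sensitivity alternative.
#' @param euler_integration use first-order Euler quaternion propagation
#'   instead of the exact exponential map (fidelity experiments only).
#' @param use_nominal_fs integrate on the nominal 1/fs grid instead of logged
#'   timestamps.
#' @return A validated list of class `stairgait_config`.
#' @export
stairgait_config <- function(stance_gyro_thr = 0.8,
                             stance_accel_thr = 1.0,
                             stance_min_s = 4 / 128,
                             stance_gap_s = 2 / 128,
                             stance_mean_factor = 0.3,
                             standstill_s = 1.5,
                             orient_process_deg = 0.4,
                             orient_meas_deg = 1.0,
                             orient_p0_deg = 5.0,
                             elev_process_m = 0.03,
                             elev_meas_m = 0.01,
                             wavelet_floor_hz = 20,
                             event_k = 3,
                             event_rel_frac = 0.25,
                             event_window_s = 0.25,
                             env_smooth_s = 0.02,
                             n_transition = 1L,
                             ke_mode = c("mean-then-square", "mean-of-squares"),
                             euler_integration = FALSE,
                             use_nominal_fs = FALSE) {
  cfg <- list(
    stance_gyro_thr = stance_gyro_thr,
    stance_accel_thr = stance_accel_thr,
    stance_min_s = stance_min_s,
    stance_gap_s = stance_gap_s,
    stance_mean_factor = stance_mean_factor,
    standstill_s = standstill_s,
    orient_process_deg = orient_process_deg,
    orient_meas_deg = orient_meas_deg,
    orient_p0_deg = orient_p0_deg,
    elev_process_m = elev_process_m,
    elev_meas_m = elev_meas_m,
    wavelet_floor_hz = wavelet_floor_hz,
    event_k = event_k,
    event_rel_frac = event_rel_frac,
    event_window_s = event_window_s,
    env_smooth_s = env_smooth_s,
    n_transition = as.integer(n_transition),
    ke_mode = match.arg(ke_mode),
    euler_integration = isTRUE(euler_integration),
    use_nominal_fs = isTRUE(use_nominal_fs)
  )
  num <- c("stance_gyro_thr", "stance_accel_thr", "stance_min_s",
           "stance_gap_s", "stance_mean_factor", "standstill_s", "orient_process_deg",
           "orient_meas_deg", "orient_p0_deg", "elev_process_m",
           "elev_meas_m", "wavelet_floor_hz", "event_k", "event_rel_frac",
           "event_window_s",
           "env_smooth_s")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || !is.finite(cfg[[f]]) ||
        cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a positive scalar", call. = FALSE)
    }
  }
  if (cfg$n_transition < 0) stop("n_transition must be >= 0", call. = FALSE)
  class(cfg) <- "stairgait_config"
  cfg
}

#' Check a configuration against a recording's sampling rate
#' @keywords internal
check_config_fs <- function(cfg, fs) {
  if (cfg$wavelet_floor_hz >= fs / 2) {
    stop("wavelet_floor_hz (", cfg$wavelet_floor_hz,
         ") must be below fs/2 = ", fs / 2, call. = FALSE)
  }
  invisible(cfg)
}

#' Stair geometry
#'
#' @param riser_m riser (step height) H, m. The staircase used as the default
#'   throughout the package has H = 0.18 m and tread depth 0.30 m.
#' @param tread_m tread (step depth), m.
#' @param n_treads number of treads in the flight.
#' @param direction `"ascent"` or `"descent"`.
#' @return A list of class `stair_geometry`.
#' @export
stair_geometry <- function(riser_m = 0.18, tread_m = 0.30, n_treads = 10L,
                           direction = c("ascent", "descent")) {
  direction <- match.arg(direction)
  if (!is.numeric(riser_m) || riser_m <= 0) stop("riser_m must be > 0")
  if (!is.numeric(tread_m) || tread_m <= 0) stop("tread_m must be > 0")
  n_treads <- as.integer(n_treads)
  if (n_treads < 1L) stop("n_treads must be >= 1")
  structure(list(riser_m = riser_m, tread_m = tread_m,
                 n_treads = n_treads, direction = direction),
            class = "stair_geometry")
}

#' @export
print.stair_geometry <- function(x, ...) {
  cat(sprintf("Stair geometry: riser %.3f m, tread %.3f m, %d treads, %s\n",
              x$riser_m, x$tread_m, x$n_treads, x$direction))
  invisible(x)
}

#' Read stair geometry or configuration overrides from JSON
#'
#' @param path JSON file. For geometry: fields `riser_m`, `tread_m`,
#'   `n_treads`, `direction`. For config: any subset of the
#'   [stairgait_config()] arguments.
#' @return `stair_geometry` or `stairgait_config` object.
#' @export
read_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  stair_geometry(riser_m = g$riser_m, tread_m = g$tread_m,
                 n_treads = if (is.null(g$n_treads)) 10L else g$n_treads,
                 direction = if (is.null(g$direction)) "ascent" else g$direction)
}

#' @rdname read_geometry
#' @export
read_config <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(stairgait_config, o)
}
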