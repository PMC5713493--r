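# Synthetic stair-running foot motion and IMU signal generator.
#
# The generator builds a piecewise-polynomial single-foot trajectory over a
# flight of stairs: a pre-run standstill, then for each stride a smooth swing
# to the next tread and a stance split into braking (landing dip, pitch
# sweep-in), a quiet mid-stance plateau (the truly stationary period), and
# propulsion (pitch sweep-out, push-off ramp), ending in a final standstill.
# Ascent swings follow a parabolic-like path with a commanded apex clearance
# over the step nose; descent swings are near-linear and the commanded
# clearance is realized by the landing dip during early stance, mirroring a
# foot rolling over the tread nose. Position, velocity and acceleration are
# evaluated analytically from the polynomial segments, so velocity is the
# exact derivative of position. Per-stride truth metrics are computed from
# the truth kinematics with the same metric definitions used on estimated
# data (single source of definitions); no estimation code is involved.

#' Simulation specification
#'
#' @param n_strides number of footfalls after the starting standstill; each
#'   advances one tread in the run direction (treads alternate between feet,
#'   so a single simulated foot advances one riser per footfall).
#' @param stride_period stride duration T, s (defaults to 0.6 s, a maximal
#'   stair-running pace).
#' @param stance_fraction stance share of the stride (0-1).
#' @param swing_clearance commanded foot clearance c, m. Defaults to 0.05 m
#'   for ascent and 0.02 m for descent.
#' @param stance_pitch_sweep_deg total monotone pitch excursion over stance
#'   (the bounce angle), deg.
#' @param v_takeoff vertical foot velocity at toe-off, m/s (default +0.5
#'   ascending, -0.4 descending).
#' @param v_landing vertical foot velocity at foot-strike, m/s.
#' @param standstill_s duration of the pre-run and post-run standstills, s.
#' @param geom a [stair_geometry()]; its `direction` selects ascent/descent.
#' @param fs sampling rate, Hz.
#' @param seed integer seed for all stochastic sensor errors.
#' @param gyro_bias_deg_s per-axis gyro bias, deg/s (length 1 or 3).
#' @param gyro_noise_density gyro white noise, deg/s/sqrt(Hz).
#' @param accel_bias_m_s2 per-axis accelerometer bias, m/s^2.
#' @param accel_noise_density accelerometer white noise, m/s^2/sqrt(Hz).
#' @param burst_accel,burst_gyro amplitude of the strike/toe-off transient
#'   bursts injected into the accelerometer (m/s^2) and gyro (rad/s).
#' @param burst_freq_hz carrier frequency of the bursts (above the 20 Hz
#'   detection floor).
#' @param burst_tau_s exponential decay constant of the bursts, s.
#' @param burst_halfwidth_s half-width of the burst support, s.
#' @param clip_g optional accelerometer saturation limit in g (e.g. 6);
#'   `NULL` disables clipping.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_strides = 10L,
                            stride_period = 0.6,
                            stance_fraction = 0.45,
                            swing_clearance = NULL,
                            stance_pitch_sweep_deg = 45,
                            v_takeoff = NULL,
                            v_landing = -0.4,
                            standstill_s = 2.0,
                            geom = NULL,
                            fs = 128,
                            seed = 1L,
                            gyro_bias_deg_s = c(0.3, 0.3, 0.3),
                            gyro_noise_density = 0.1,
                            accel_bias_m_s2 = c(0.03, 0.03, 0.03),
                            accel_noise_density = 0.01,
                            burst_accel = 60,
                            burst_gyro = 3,
                            burst_freq_hz = 40,
                            burst_tau_s = 0.010,
                            burst_halfwidth_s = 0.015,
                            clip_g = NULL) {
  if (is.null(geom)) geom <- stair_geometry(n_treads = n_strides)
  ascent <- geom$direction == "ascent"
  if (is.null(swing_clearance)) swing_clearance <- if (ascent) 0.05 else 0.02
  if (is.null(v_takeoff)) v_takeoff <- if (ascent) 0.5 else -0.4
  spec <- list(
    n_strides = as.integer(n_strides), stride_period = stride_period,
    stance_fraction = stance_fraction, swing_clearance = swing_clearance,
    stance_pitch_sweep_deg = stance_pitch_sweep_deg,
    v_takeoff = v_takeoff, v_landing = v_landing,
    standstill_s = standstill_s, geom = geom, fs = fs, seed = as.integer(seed),
    gyro_bias_deg_s = rep_len(gyro_bias_deg_s, 3),
    gyro_noise_density = gyro_noise_density,
    accel_bias_m_s2 = rep_len(accel_bias_m_s2, 3),
    accel_noise_density = accel_noise_density,
    burst_accel = burst_accel, burst_gyro = burst_gyro,
    burst_freq_hz = burst_freq_hz, burst_tau_s = burst_tau_s,
    burst_halfwidth_s = burst_halfwidth_s, clip_g = clip_g)
  if (spec$n_strides < 1) stop("n_strides must be >= 1", call. = FALSE)
  if (!(spec$stance_fraction > 0 && spec$stance_fraction < 1)) {
    stop("stance_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (spec$fs <= 40) stop("fs must exceed 40 Hz", call. = FALSE)
  if (spec$swing_clearance <= 0) stop("swing_clearance must be > 0", call. = FALSE)
  if (spec$gyro_noise_density < 0 || spec$accel_noise_density < 0) {
    stop("noise densities must be >= 0", call. = FALSE)
  }
  if (spec$v_landing >= 0) stop("v_landing must be negative (foot lands downward)",
                                call. = FALSE)
  class(spec) <- "simulation_spec"
  spec
}

# ---- piecewise polynomial machinery ---------------------------------------

#' Quintic Hermite coefficients for (p, v, a) boundary conditions
#' @keywords internal
hermite_quintic <- function(p0, v0, a0, p1, v1, a1, T) {
  c012 <- c(p0, v0, a0 / 2)
  A <- rbind(c(T^3, T^4, T^5),
             c(3 * T^2, 4 * T^3, 5 * T^4),
             c(6 * T, 12 * T^2, 20 * T^3))
  b <- c(p1 - (c012[1] + c012[2] * T + c012[3] * T^2),
         v1 - (c012[2] + 2 * c012[3] * T),
         a1 - 2 * c012[3])
  c(c012, solve(A, b))
}

# 64 u^3 (1-u)^3 in local time: zero value/slope/curvature at both ends,
# unit maximum at the segment midpoint.
#' @keywords internal
bump_poly <- function(T) {
  cu <- 64 * c(0, 0, 0, 1, -3, 3, -1)
  cu / T^(seq_along(cu) - 1)
}

#' @keywords internal
poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b)))
}

#' @keywords internal
poly_min_max <- function(coef, T, n_grid = 2048) {
  u <- seq(0, T, length.out = n_grid)
  y <- polyval_inc(coef, u)
  list(min = min(y), max = max(y),
       t_min = u[which.min(y)], t_max = u[which.max(y)])
}

# ---- trajectory construction ----------------------------------------------

#' Simulate ground-truth stair-running foot motion
#'
#' @param spec a [simulation_spec()].
#' @return Object of class `ground_truth`: list with per-sample `t`, `p`,
#'   `v`, `a` (navigation frame), `q` (true orientation), `omega` (true body
#'   rates), `pitch` (rad); `events` (per-footfall truth: strike/off times,
#'   tread, quiet-window bounds); `metrics` (per-stride truth metrics
#'   computed with the package's metric definitions); and the `spec`.
#' @export
simulate_foot_trajectory <- function(spec) {
  fs <- spec$fs
  T <- spec$stride_period
  Ts <- spec$stance_fraction * T
  tau_b <- 0.4 * Ts; tau_q <- 0.2 * Ts; tau_p <- 0.4 * Ts
  tau_sw <- (1 - spec$stance_fraction) * T
  if (tau_sw * fs <= 4) {
    stop("swing duration too short for the sampling rate (<= 4 samples)",
         call. = FALSE)
  }
  ascent <- spec$geom$direction == "ascent"
  H <- spec$geom$riser_m * (if (ascent) 1 else -1)
  D <- spec$geom$tread_m
  S <- deg2rad(spec$stance_pitch_sweep_deg)
  v_to <- spec$v_takeoff; v_ld <- spec$v_landing
  dz_p <- 0.3 * v_to * tau_p   # push-off elevation ramp

  # braking dip (relative to tread level): natural quintic, plus a commanded
  # bump for descent so the dip depth equals the commanded clearance
  brake_rel <- hermite_quintic(0, v_ld, 0, 0, 0, 0, tau_b)
  d_nat <- -poly_min_max(brake_rel, tau_b)$min
  if (!ascent) {
    target <- spec$swing_clearance
    g <- function(B) -poly_min_max(poly_add(brake_rel, B * bump_poly(tau_b)),
                                   tau_b)$min - target
    B_b <- stats::uniroot(g, c(-(target + 1), 1), tol = 1e-12)$root
    brake_rel <- poly_add(brake_rel, B_b * bump_poly(tau_b))
    d_eff <- target
  } else {
    d_eff <- d_nat
  }

  # swing path (relative to the target tread level): Hermite base plus an
  # apex bump solved so the ascent apex clears the nose by the commanded
  # clearance above the stance minimum
  swing_rel <- hermite_quintic(-H + dz_p, v_to, 0, 0, v_ld, 0, tau_sw)
  if (ascent) {
    apex_target <- spec$swing_clearance - d_eff
    if (apex_target <= 0) {
      stop("swing_clearance must exceed the landing dip depth (",
           signif(d_eff, 3), " m)", call. = FALSE)
    }
    f <- function(B) poly_min_max(poly_add(swing_rel, B * bump_poly(tau_sw)),
                                  tau_sw)$max - apex_target
    lo <- -1; hi <- 1
    while (f(lo) > 0) lo <- lo * 2
    while (f(hi) < 0) hi <- hi * 2
    B_sw <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    swing_rel <- poly_add(swing_rel, B_sw * bump_poly(tau_sw))
  }

  n <- spec$n_strides
  segs <- list()
  add_seg <- function(dur, y, z, th) {
    segs[[length(segs) + 1]] <<- list(dur = dur, y = y, z = z, th = th)
  }
  const <- function(v) v  # degree-0 polynomial

  # pre-run standstill + initial push-off
  add_seg(spec$standstill_s, const(0), const(0), const(0))
  add_seg(tau_p, const(0),
          hermite_quintic(0, 0, 0, dz_p, v_to, 0, tau_p),
          hermite_quintic(0, 0, 0, -S / 2, 0, 0, tau_p))
  for (k in seq_len(n)) {
    zk <- k * H; yk <- k * D
    add_seg(tau_sw,
            hermite_quintic((k - 1) * D, 0, 0, yk, 0, 0, tau_sw),
            poly_add(swing_rel, c(zk)),
            hermite_quintic(-S / 2, 0, 0, S / 2, 0, 0, tau_sw))
    add_seg(tau_b, const(yk), poly_add(brake_rel, c(zk)),
            hermite_quintic(S / 2, 0, 0, 0, 0, 0, tau_b))
    if (k < n) {
      add_seg(tau_q, const(yk), const(zk), const(0))
      add_seg(tau_p, const(yk),
              hermite_quintic(zk, 0, 0, zk + dz_p, v_to, 0, tau_p),
              hermite_quintic(0, 0, 0, -S / 2, 0, 0, tau_p))
    } else {
      add_seg(tau_q + spec$standstill_s, const(yk), const(zk), const(0))
    }
  }

  durs <- vapply(segs, `[[`, numeric(1), "dur")
  starts <- cumsum(c(0, durs[-length(durs)]))
  total <- sum(durs)
  t <- seq(0, total, by = 1 / fs)
  seg_of <- pmin(findInterval(t, starts), length(segs))
  N <- length(t)
  y <- z <- th <- dy <- dz <- dth <- ddy <- ddz <- numeric(N)
  for (s in seq_along(segs)) {
    idx <- which(seg_of == s)
    if (!length(idx)) next
    tau <- t[idx] - starts[s]
    for (comp in c("y", "z", "th")) {
      cf <- segs[[s]][[comp]]
      d1 <- polyderiv_inc(cf); d2 <- polyderiv_inc(d1)
      val <- polyval_inc(cf, tau)
      vel <- polyval_inc(d1, tau)
      acc <- polyval_inc(d2, tau)
      if (comp == "y") { y[idx] <- val; dy[idx] <- vel; ddy[idx] <- acc }
      if (comp == "z") { z[idx] <- val; dz[idx] <- vel; ddz[idx] <- acc }
      if (comp == "th") { th[idx] <- val; dth[idx] <- vel }
    }
  }
  p <- cbind(0, y, z); v <- cbind(0, dy, dz); a <- cbind(0, ddy, ddz)
  dimnames(p) <- dimnames(v) <- dimnames(a) <- NULL
  q <- quat_from_euler(0, th, 0)
  omega <- cbind(-dth, 0, 0)
  dimnames(omega) <- NULL

  # truth event schedule (segment index bookkeeping):
  # segment layout: 1 standstill, 2 push-off, then per stride k:
  # swing, braking, [quiet, push-off | final quiet]
  seg_base <- function(k) 2L + (k - 1L) * 4L  # last segment before stride k's swing
  strike <- vapply(seq_len(n), function(k) starts[seg_base(k) + 2L], 0)
  off <- c(starts[3L],  # end of the initial push-off = start of first swing
           vapply(seq_len(n), function(k) {
             if (k < n) starts[seg_base(k) + 4L] + durs[seg_base(k) + 4L]
             else NA_real_
           }, 0))
  quiet_start <- c(0, vapply(seq_len(n), function(k)
    starts[seg_base(k) + 3L], 0))
  quiet_end <- c(starts[2L], vapply(seq_len(n), function(k)
    starts[seg_base(k) + 3L] + (if (k < n) tau_q else tau_q + spec$standstill_s),
    0))
  events <- data.frame(
    footfall = 0:n,
    tread = (0:n) * (if (ascent) 1 else -1),
    t_strike = c(NA_real_, strike),
    t_off = off,
    quiet_start = quiet_start,
    quiet_end = quiet_end)

  truth <- structure(list(
    t = t, p = p, v = v, a = a, q = q, omega = omega, pitch = th,
    events = events, spec = spec,
    clearance_cmd = spec$swing_clearance, dip_depth = d_eff),
    class = "ground_truth")
  truth$metrics <- truth_metrics(truth)
  truth
}

#' Per-stride truth metrics from truth kinematics
#'
#' Applies the package's metric definitions (extrema location, clearance,
#' kinetic-energy proxy, bounce angles, GRF proxy, timing identities) to the
#' noise-free truth series with the truth event times.
#' @keywords internal
truth_metrics <- function(truth) {
  ev <- truth$events
  n <- nrow(ev) - 1L
  events <- data.frame(
    stride_id = seq_len(n),
    side = "unknown",
    run_id = 1L,
    t_strike = ev$t_strike[-1],
    t_off = ev$t_off[-1],
    is_transition = c(TRUE, rep(FALSE, max(0L, n - 2L)), TRUE)[seq_len(n)])
  class(events) <- c("gait_events", "data.frame")
  traj <- trajectory_series(truth$t, truth$a, truth$v, truth$p,
                            stage = "elevation")
  orient <- orientation_series(truth$t, truth$q)
  assemble_metrics(traj, orient, events, truth$spec$geom$direction,
                   drop_transition = FALSE)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth: %d strides %s, %.1f s @ %g Hz, riser %.2f m\n",
    x$spec$n_strides, x$spec$geom$direction, x$t[length(x$t)], x$spec$fs,
    x$spec$geom$riser_m))
  invisible(x)
}

# ---- IMU synthesis --------------------------------------------------------

#' Synthesize IMU signals from ground truth
#'
#' Inverts the navigation equation: the noise-free specific force is
#' \eqn{a_f = R(q)^T (a_{nav} + [0,0,G])} and the noise-free rate is the true
#' body rate, so running the pipeline's frame rotation on the clean signals
#' reproduces the truth acceleration exactly. Sensor errors are then added:
#' per-axis bias, seeded Gaussian white noise scaled to the sampling
#' bandwidth, and short exponentially decaying bursts at the true
#' strike/toe-off times (carrier above 20 Hz) that give the wavelet detector
#' realistic transients with known timing. Optional saturation clipping
#' mimics a limited measurement range.
#'
#' @param truth a `ground_truth` from [simulate_foot_trajectory()].
#' @param spec the [simulation_spec()] (defaults to the one inside `truth`).
#' @param side recorded side label.
#' @return An [imu_recording()].
#' @export
synthesize_imu <- function(truth, spec = truth$spec, side = "unknown") {
  G <- STANDARD_GRAVITY
  grav <- cbind(truth$a[, 1], truth$a[, 2], truth$a[, 3] + G)
  accel <- quat_rotate(quat_conjugate(truth$q), grav)
  gyro <- truth$omega
  t <- truth$t
  fs <- spec$fs

  ev_times <- stats::na.omit(c(truth$events$t_strike, truth$events$t_off))
  burst <- numeric(length(t))
  for (te in ev_times) {
    idx <- which(abs(t - te) <= spec$burst_halfwidth_s)
    if (!length(idx)) next
    dt <- t[idx] - te
    # odd carrier under an even envelope: zero net impulse, so the burst
    # excites the detection band without corrupting the integrated physics
    burst[idx] <- burst[idx] +
      exp(-abs(dt) / spec$burst_tau_s) * sin(2 * pi * spec$burst_freq_hz * dt)
  }
  # the ring is carried mostly by the lateral accelerometer axis and the
  # roll/yaw gyro axes: the detector only consumes the magnitude channels,
  # while the metric-bearing components (vertical/forward velocity, pitch)
  # see realistic, small vibration residues rather than a 0.2 m/s excursion
  accel <- accel + burst %o% (spec$burst_accel * c(1.0, 0.25, 0.25))
  gyro <- gyro + burst %o% (spec$burst_gyro * c(0.15, 0.5, 1.0))

  sg <- deg2rad(spec$gyro_noise_density) * sqrt(fs)
  sa <- spec$accel_noise_density * sqrt(fs)
  local_seed(spec$seed, {
    gyro <- gyro + matrix(stats::rnorm(length(gyro), 0, sg), ncol = 3)
    accel <- accel + matrix(stats::rnorm(length(accel), 0, sa), ncol = 3)
  })
  gyro <- sweep(gyro, 2, -deg2rad(spec$gyro_bias_deg_s))
  accel <- sweep(accel, 2, -spec$accel_bias_m_s2)
  if (!is.null(spec$clip_g)) {
    lim <- spec$clip_g * G
    accel <- pmin(pmax(accel, -lim), lim)
  }
  imu_recording(t, accel, gyro, fs = fs, side = side, gravity_mag = G)
}

#' Simulate a full run: ground truth plus noisy IMU recording
#'
#' @param spec a [simulation_spec()].
#' @param side recorded side label.
#' @return List with elements `truth` and `recording`.
#' @export
simulate_run <- function(spec = simulation_spec(), side = "unknown") {
  truth <- simulate_foot_trajectory(spec)
  list(truth = truth, recording = synthesize_imu(truth, spec, side = side))
}

#' Write ground truth (events + per-stride truth metrics) to CSV
#' @param truth a `ground_truth`.
#' @param path_events,path_metrics output CSV paths.
#' @export
write_ground_truth <- function(truth, path_events, path_metrics) {
  utils::write.csv(truth$events, path_events, row.names = FALSE)
  utils::write.csv(truth$metrics, path_metrics, row.names = FALSE)
  invisible(c(path_events, path_metrics))
}
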