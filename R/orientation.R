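# Orientation estimation: quaternion strapdown integration of the gyro,
# corrected for roll/pitch drift by accelerometer tilt observations in a
# 2-state Kalman filter gated on the stationary periods. Yaw is carried from
# the gyro untouched: it is unobservable from the accelerometer and no
# magnetometer is used.

#' Integrate the quaternion kinematic equation
#'
#' Propagates \eqn{\dot q = \tfrac12\, q \circ \Omega},
#' \eqn{\Omega = [0, \omega_f]}, using the closed-form exponential-map update
#' \eqn{q_{k+1} = q_k \circ \exp([\,\bar\omega_k \Delta t\,]/2)} with the
#' midpoint rate \eqn{\bar\omega_k = (\omega_k + \omega_{k+1})/2}, and
#' renormalizes at every step. A first-order Euler scheme is available behind
#' `cfg$euler_integration` for fidelity experiments; the exponential map
#' removes the integration-scheme error for fast foot rotations at 128 Hz.
#'
#' @param q0 initial unit quaternion (w, x, y, z).
#' @param gyro n x 3 angular rate, rad/s, IMU frame.
#' @param t sample times, s.
#' @param euler_scheme use first-order Euler propagation instead of the exact
#'   exponential map.
#' @return Object of class `orientation_series`: list with `t`, `q` (n x 4
#'   unit quaternions) and `euler` (data.frame `roll`, `pitch`, `yaw`, rad).
#' @export
integrate_quaternion <- function(q0, gyro, t, euler_scheme = FALSE) {
  gyro <- as.matrix(gyro)
  n <- length(t)
  if (n == 0 || nrow(gyro) != n) {
    stop("gyro and t must be non-empty and of matching length", call. = FALSE)
  }
  if (abs(sqrt(sum(q0^2)) - 1) > 1e-6) stop("q0 must be a unit quaternion")
  q <- matrix(0, n, 4)
  q[1, ] <- quat_normalize(q0)
  if (n > 1) {
    for (k in seq_len(n - 1)) {
      dt <- t[k + 1] - t[k]
      w <- (gyro[k, ] + gyro[k + 1, ]) / 2
      if (euler_scheme) {
        dq <- quat_multiply(q[k, ], c(0, w)) / 2
        q[k + 1, ] <- quat_normalize(q[k, ] + dq * dt)
      } else {
        q[k + 1, ] <- quat_normalize(quat_multiply(q[k, ], quat_exp_rate(w, dt)))
      }
    }
  }
  orientation_series(t, q)
}

#' @keywords internal
orientation_series <- function(t, q, updates = NULL) {
  structure(list(t = t, q = q, euler = euler_from_quat(q), updates = updates),
            class = "orientation_series")
}

#' @export
print.orientation_series <- function(x, ...) {
  rng <- range(rad2deg(x$euler$pitch))
  cat(sprintf("Orientation series: %d samples, pitch range [%.1f, %.1f] deg%s\n",
              length(x$t), rng[1], rng[2],
              if (is.null(x$updates)) "" else
                sprintf(", %d tilt updates", nrow(x$updates))))
  invisible(x)
}

#' Accelerometer tilt observation
#'
#' During a stationary period the accelerometer measures the components of
#' gravity, giving the tilt angles
#' \deqn{\phi_a = \sin^{-1}(a_x / G), \qquad
#'       \theta_a = -\sin^{-1}\!\big(a_y / (G\cos\phi_a)\big),}
#' with both arguments clamped to \eqn{[-1, 1]}. The observation is flagged
#' invalid near gimbal tilt (`cos(phi_a)` below `eps`), where pitch is
#' unobservable.
#'
#' @param accel length-3 specific force (or interval mean), m/s^2.
#' @param G gravity magnitude, m/s^2.
#' @param eps validity floor on `cos(phi_a)`.
#' @return List with `roll_a`, `pitch_a` (rad) and `valid`.
#' @export
accel_tilt <- function(accel, G = STANDARD_GRAVITY, eps = 0.05) {
  roll_a <- asin(clamp1(accel[1] / G))
  cr <- cos(roll_a)
  if (cr < eps) {
    return(list(roll_a = roll_a, pitch_a = NA_real_, valid = FALSE))
  }
  pitch_a <- -asin(clamp1(accel[2] / (G * cr)))
  list(roll_a = roll_a, pitch_a = pitch_a, valid = TRUE)
}

#' Fuse gyro orientation with accelerometer tilt in a Kalman filter
#'
#' Between stance periods the quaternion is propagated from the gyro exactly
#' as in [integrate_quaternion()] while the 2-state tilt covariance grows
#' with the configured random-walk intensity. Once per stationary interval
#' (at the interval's midpoint sample) a linear Kalman update blends the
#' gyro-derived roll/pitch with the tilt observed from the interval-mean
#' accelerometer reading; the update is applied once per interval rather than
#' per sample because stance accelerometer samples are serially correlated
#' and per-sample updating would double-count the observation. The corrected
#' roll/pitch are re-embedded into the quaternion with the gyro yaw
#' untouched.
#'
#' @param rec an [imu_recording()].
#' @param mask a `stationary_mask` from [detect_stationary()].
#' @param cfg a [stairgait_config()].
#' @param q0 initial orientation; by default derived from the tilt observed
#'   over the first stationary interval (yaw 0), matching an initialization
#'   where the navigation frame coincides with the IMU frame up to tilt.
#' @return An `orientation_series`; element `updates` logs time, innovation
#'   and gain of every measurement update.
#' @export
fuse_orientation <- function(rec, mask, cfg = stairgait_config(), q0 = NULL) {
  t <- rec$t
  n <- length(t)
  iv <- mask$intervals
  if (nrow(iv) == 0) stop("stationary mask is empty", call. = FALSE)
  interval_mean_accel <- function(i) {
    colMeans(rec$accel[iv[i, 1]:(iv[i, 2] - 1L), , drop = FALSE])
  }
  if (is.null(q0)) {
    tl <- accel_tilt(interval_mean_accel(1), rec$gravity_mag)
    if (!tl$valid) stop("initial tilt observation invalid (near-gimbal)",
                        call. = FALSE)
    q0 <- quat_from_euler(tl$roll_a, tl$pitch_a, 0)
  }
  # midpoint sample of each interval; updates applied when propagation
  # reaches that sample
  mid_idx <- pmin(iv[, 1] + (iv[, 2] - 1L - iv[, 1]) %/% 2L, n)
  upd_at <- integer(n)
  upd_at[mid_idx] <- seq_len(nrow(iv))

  qc <- deg2rad(cfg$orient_process_deg)^2     # rad^2 per s
  Rm <- diag(deg2rad(cfg$orient_meas_deg)^2, 2)
  P <- diag(deg2rad(cfg$orient_p0_deg)^2, 2)
  q <- matrix(0, n, 4)
  q[1, ] <- quat_normalize(q0)
  updates <- list()

  do_update <- function(k) {
    i <- upd_at[k]
    z <- accel_tilt(interval_mean_accel(i), rec$gravity_mag)
    if (!z$valid) return(FALSE)
    eul <- euler_from_quat(q[k, ])
    x <- c(eul$roll, eul$pitch)
    innov <- wrap_angle(c(z$roll_a, z$pitch_a) - x)
    K <- P %*% solve(P + Rm)
    xh <- x + as.numeric(K %*% innov)
    q[k, ] <<- quat_from_euler(xh[1], xh[2], eul$yaw)
    P <<- (diag(2) - K) %*% P
    P <<- (P + t(P)) / 2
    yaw_post <- euler_from_quat(q[k, ])$yaw
    updates[[length(updates) + 1]] <<- data.frame(
      t = t[k], innov_roll = innov[1], innov_pitch = innov[2],
      gain_roll = K[1, 1], gain_pitch = K[2, 2],
      yaw_pre = eul$yaw, yaw_post = yaw_post)
    TRUE
  }

  if (upd_at[1] > 0) do_update(1)
  if (n > 1) {
    for (k in seq_len(n - 1)) {
      dt <- t[k + 1] - t[k]
      w <- (rec$gyro[k, ] + rec$gyro[k + 1, ]) / 2
      if (cfg$euler_integration) {
        dq <- quat_multiply(q[k, ], c(0, w)) / 2
        q[k + 1, ] <- quat_normalize(q[k, ] + dq * dt)
      } else {
        q[k + 1, ] <- quat_normalize(quat_multiply(q[k, ], quat_exp_rate(w, dt)))
      }
      P <- P + diag(qc * dt, 2)
      if (upd_at[k + 1] > 0) do_update(k + 1)
    }
  }
  orientation_series(t, q, updates = do.call(rbind, updates))
}
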