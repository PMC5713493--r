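# Per-stride kinematic and kinetic metrics computed from the corrected
# trajectory, the filtered orientation and the detected gait events.

#' Locate the per-stride elevation extrema
#'
#' `t_min` is the minimizer of foot elevation on `[t_strike, t_off]`
#' (earliest sample on ties). For ascent, `t_max` is the last local maximum
#' of elevation in the swing window preceding the strike (the foot's apex
#' over the step nose); for descent it is the first local maximum on
#' `[t_strike, t_off]` (the foot rolls over the nose during early stance),
#' falling back to the window up to the next strike, and finally to the plain
#' window maximum with `fallback = TRUE`.
#'
#' @param traj a `trajectory_series` at stage `"elevation"`.
#' @param events a `gait_events` table (with [stride_times()] applied).
#' @param direction `"ascent"` or `"descent"`.
#' @param swing_lookback_s swing search window before the strike used when no
#'   preceding toe-off is available, s.
#' @return data.frame with one row per event row: `t_max`, `t_min`,
#'   `fallback`.
#' @export
locate_extrema <- function(traj, events, direction = c("ascent", "descent"),
                           swing_lookback_s = 0.45) {
  direction <- match.arg(direction)
  if (!identical(traj$stage, "elevation")) {
    stop("extrema are located on the elevation-corrected trajectory",
         call. = FALSE)
  }
  t <- traj$t
  pz <- traj$p[, 3]
  n <- nrow(events)
  t_max <- t_min <- rep(NA_real_, n)
  fallback <- logical(n)
  for (i in seq_len(n)) {
    ts <- events$t_strike[i]; to <- events$t_off[i]
    if (is.na(ts) || is.na(to)) next
    i_s <- nearest_index(t, ts); i_o <- nearest_index(t, to)
    stance <- pz[i_s:i_o]
    t_min[i] <- t[i_s + which.min(stance) - 1L]
    if (direction == "ascent") {
      lo_t <- if (i > 1 && !is.na(events$t_off[i - 1]) &&
                  events$run_id[i - 1] == events$run_id[i]) {
        events$t_off[i - 1]
      } else ts - swing_lookback_s
      i_lo <- max(1L, nearest_index(t, lo_t))
      win <- pz[i_lo:i_s]
      k <- local_maxima(win)
      if (length(k)) {
        t_max[i] <- t[i_lo + k[length(k)] - 1L]
      } else {
        t_max[i] <- t[i_lo + which.max(win) - 1L]
        fallback[i] <- TRUE
      }
    } else {
      k <- local_maxima(stance)
      if (length(k)) {
        t_max[i] <- t[i_s + k[1] - 1L]
      } else {
        i_next <- if (i < n && !is.na(events$t_strike[i + 1])) {
          nearest_index(t, events$t_strike[i + 1]) - 1L
        } else i_o
        win <- pz[i_s:i_next]
        k2 <- local_maxima(win)
        if (length(k2)) {
          t_max[i] <- t[i_s + k2[1] - 1L]
        } else {
          t_max[i] <- t[i_s + which.max(win) - 1L]
        }
        fallback[i] <- TRUE
      }
    }
  }
  data.frame(t_max = t_max, t_min = t_min, fallback = fallback)
}

#' Interior local maxima of a series, plateau-aware
#'
#' Returns the first index of every maximal plateau that is strictly higher
#' than both neighbours of the plateau.
#' @keywords internal
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Foot clearance
#'
#' \eqn{c = p_z(t_{max}) - p_z(t_{min})}, nearest-sample lookup on the
#' elevation-corrected trajectory.
#'
#' @param traj a `trajectory_series` with position present.
#' @param t_max,t_min extremum times, s.
#' @return Clearance, m.
#' @export
clearance <- function(traj, t_max, t_min) {
  pz <- traj$p[, 3]
  pz[nearest_index(traj$t, t_max)] - pz[nearest_index(traj$t, t_min)]
}

#' Kinetic-energy proxy per unit mass
#'
#' The squared stride-averaged foot speed over two,
#' \eqn{ke_m = \overline{\lVert v\rVert}^{\,2} / 2} ((m/s)^2): the mean of
#' the speed magnitude is taken first and then squared. The alternative
#' mean-of-squares reading is available via `mode` for sensitivity studies
#' and gives strictly larger values whenever speed varies over the stride.
#'
#' @param traj a `trajectory_series` with velocity present.
#' @param t_start,t_end stride window (half-open), s.
#' @param mode `"mean-then-square"` (the definition) or `"mean-of-squares"`.
#' @return Kinetic-energy proxy, (m/s)^2.
#' @export
kinetic_energy_proxy <- function(traj, t_start, t_end,
                                 mode = c("mean-then-square",
                                          "mean-of-squares")) {
  mode <- match.arg(mode)
  sel <- traj$t >= t_start & traj$t < t_end
  if (!any(sel)) stop("empty stride window", call. = FALSE)
  speed <- row_norm(traj$v[sel, , drop = FALSE])
  if (mode == "mean-then-square") mean(speed)^2 / 2 else mean(speed^2) / 2
}

#' Bounce angles
#'
#' Pitch excursions over stance:
#' \eqn{\theta_{break} = |\theta(t_{strike}) - \theta(t_{min})|},
#' \eqn{\theta_{prop} = |\theta(t_{off}) - \theta(t_{min})|},
#' \eqn{\theta_{bounce} = \theta_{break} + \theta_{prop}}. Pitch is unwrapped
#' over the stance window before differencing. Reported in degrees.
#'
#' @param orient an `orientation_series`.
#' @param t_strike,t_min,t_off event times, ordered
#'   `t_strike <= t_min <= t_off`.
#' @return Named list `theta_break_deg`, `theta_prop_deg`,
#'   `theta_bounce_deg`.
#' @export
bounce_angles <- function(orient, t_strike, t_min, t_off) {
  i_s <- nearest_index(orient$t, t_strike)
  i_m <- nearest_index(orient$t, t_min)
  i_o <- nearest_index(orient$t, t_off)
  if (!(i_s <= i_m && i_m <= i_o)) {
    stop("times must satisfy t_strike <= t_min <= t_off", call. = FALSE)
  }
  pitch <- unwrap_angle(orient$euler$pitch[i_s:i_o])
  th_s <- pitch[1]
  th_m <- pitch[i_m - i_s + 1L]
  th_o <- pitch[length(pitch)]
  br <- abs(rad2deg(th_s - th_m))
  pr <- abs(rad2deg(th_o - th_m))
  list(theta_break_deg = br, theta_prop_deg = pr, theta_bounce_deg = br + pr)
}

#' Ground-reaction-force proxy per unit mass
#'
#' The net vertical impulse per unit mass over stance divided by the stance
#' time: \eqn{gf_m = (v_z(t_{off}) - v_z(t_{strike})) / t_{stance}}, N/kg.
#' This is the net change of vertical momentum; no gravity term is added, so
#' a momentum-preserving stance (descent) yields values near zero while an
#' upward push-off (ascent) yields positive values.
#'
#' @param traj a `trajectory_series` with velocity present.
#' @param t_strike,t_off stance boundary times, s (`t_strike < t_off`).
#' @return gf_m, N/kg.
#' @export
grf_proxy <- function(traj, t_strike, t_off) {
  if (!(t_strike < t_off)) stop("need t_strike < t_off", call. = FALSE)
  vz <- traj$v[, 3]
  dv <- vz[nearest_index(traj$t, t_off)] - vz[nearest_index(traj$t, t_strike)]
  dv / (t_off - t_strike)
}

#' Assemble the per-stride metrics table
#'
#' Joins the timing variables with the kinematic and kinetic metrics, one row
#' per stride. Transition strides (first and last footfall of each run) and
#' strides without a successor strike are excluded by default, mirroring the
#' steady-state protocol; left and right feet are pooled by row-binding
#' tables with the `side` column preserved.
#'
#' @param traj a `trajectory_series` at stage `"elevation"`.
#' @param orient the `orientation_series` used for the trajectory.
#' @param events a `gait_events` table with [stride_times()] applied.
#' @param direction `"ascent"` or `"descent"`.
#' @param cfg a [stairgait_config()].
#' @param drop_transition exclude transition and incomplete strides.
#' @return data.frame of class `stride_metrics`.
#' @export
assemble_metrics <- function(traj, orient, events,
                             direction = c("ascent", "descent"),
                             cfg = stairgait_config(),
                             drop_transition = TRUE) {
  direction <- match.arg(direction)
  if (!"t_stride" %in% names(events)) events <- stride_times(events)
  ext <- locate_extrema(traj, events, direction)
  n <- nrow(events)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    e <- events[i, ]
    complete <- !is.na(e$t_stride) && !is.na(e$t_off) && !is.na(ext$t_min[i]) &&
      !is.na(ext$t_max[i])
    ke <- cl <- gf <- NA_real_
    ang <- list(theta_break_deg = NA_real_, theta_prop_deg = NA_real_,
                theta_bounce_deg = NA_real_)
    if (complete) {
      cl <- clearance(traj, ext$t_max[i], ext$t_min[i])
      ke <- kinetic_energy_proxy(traj, e$t_strike, e$t_strike + e$t_stride,
                                 mode = cfg$ke_mode)
      ang <- bounce_angles(orient, e$t_strike, ext$t_min[i], e$t_off)
      gf <- grf_proxy(traj, e$t_strike, e$t_off)
    }
    rows[[i]] <- data.frame(
      stride_id = e$stride_id, side = e$side, run_id = e$run_id,
      t_strike = e$t_strike, t_off = e$t_off,
      t_stride = e$t_stride, t_stance = e$t_stance, t_swing = e$t_swing,
      t_ps = e$t_ps,
      t_max = ext$t_max[i], t_min = ext$t_min[i],
      clearance_m = cl, ke_m = ke,
      theta_break_deg = ang$theta_break_deg,
      theta_prop_deg = ang$theta_prop_deg,
      theta_bounce_deg = ang$theta_bounce_deg,
      gf_m = gf,
      is_transition = e$is_transition,
      extrema_fallback = ext$fallback[i])
  }
  out <- do.call(rbind, rows)
  if (drop_transition && !is.null(out)) {
    out <- out[!out$is_transition & !is.na(out$t_stride), , drop = FALSE]
    if (nrow(out) == 0) {
      warning("no steady-state strides left after transition exclusion",
              call. = FALSE)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("stride_metrics", "data.frame")
  out
}

#' Pool stride metrics tables (e.g. left and right foot)
#'
#' @param ... `stride_metrics` tables.
#' @return A single row-bound `stride_metrics` table.
#' @export
pool_metrics <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("stride_metrics", "data.frame")
  out
}

#' @export
print.stride_metrics <- function(x, ...) {
  cat(sprintf("Stride metrics: %d strides", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(" | t_stride %.3f s, t_ps %.1f%%, c %.3f m, ke %.3f, gf %.2f N/kg (means)",
                mean(x$t_stride, na.rm = TRUE), mean(x$t_ps, na.rm = TRUE),
                mean(x$clearance_m, na.rm = TRUE), mean(x$ke_m, na.rm = TRUE),
                mean(x$gf_m, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}
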