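# Gait event detection. Foot-strike and toe-off generate broadband transients
# with substantial content above ~20 Hz, unlike mid-stance and mid-swing. An
# undecimated (a trous) wavelet detail transform isolates that band; squared
# detail coefficients of the accelerometer and gyroscope magnitude channels
# are summed and smoothed into a nonnegative envelope whose peaks mark the
# events. The transform is shift-invariant, which is what makes the peak
# times trustworthy to a few samples.

# Symmlet sym4 analysis filters (8 taps, four vanishing moments, least
# asymmetric). Four vanishing moments keep low-frequency gait content out of
# the detail bands (a short db2 leaks >10% of it), and the near-linear phase
# keeps transient peaks centred, which the event timing depends on.
SYM4_LO <- c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
             0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
             -0.012603967262037833, 0.0322231006040427)
SYM4_HI <- c(-0.0322231006040427, -0.012603967262037833, 0.09921954357684722,
             0.29785779560527736, -0.8037387518059161, 0.49761866763201545,
             0.02963552764599851, -0.07576571478927333)

#' Undecimated wavelet detail energy of one channel
#'
#' Sums squared detail coefficients over the levels whose passbands lie above
#' `floor_hz` (level j spans roughly `fs/2^(j+1)` to `fs/2^j`).
#' @keywords internal
swt_detail_energy <- function(x, fs, floor_hz) {
  n_levels <- max(1L, floor(log2((fs / 2) / floor_hz)) + 1L)
  approx_coef <- x
  energy <- numeric(length(x))
  for (j in seq_len(n_levels)) {
    dilate <- 2L^(j - 1L)
    hi <- rep(0, (length(SYM4_HI) - 1L) * dilate + 1L)
    hi[seq(1, length(hi), by = dilate)] <- SYM4_HI
    lo <- rep(0, (length(SYM4_LO) - 1L) * dilate + 1L)
    lo[seq(1, length(lo), by = dilate)] <- SYM4_LO
    energy <- energy + conv_centered(approx_coef, hi)^2
    approx_coef <- conv_centered(approx_coef, lo)
  }
  energy
}

#' High-frequency wavelet envelope for gait event detection
#'
#' @param rec an [imu_recording()].
#' @param cfg a [stairgait_config()]; uses `wavelet_floor_hz` (default 20 Hz,
#'   must be below fs/2) and `env_smooth_s`.
#' @return Object of class `event_envelope`: list with `t`, `env`
#'   (nonnegative per-sample envelope) and `fs`.
#' @export
wavelet_event_signal <- function(rec, cfg = stairgait_config()) {
  check_config_fs(cfg, rec$fs)
  channels <- cbind(row_norm(rec$accel), row_norm(rec$gyro))
  env <- numeric(length(rec$t))
  for (j in seq_len(ncol(channels))) {
    env <- env + swt_detail_energy(channels[, j], rec$fs, cfg$wavelet_floor_hz)
  }
  env <- moving_average(env, round(cfg$env_smooth_s * rec$fs))
  env <- pmax(env, 0)
  structure(list(t = rec$t, env = env, fs = rec$fs), class = "event_envelope")
}

#' @keywords internal
window_peak <- function(env, lo, hi, thr, first = FALSE, rel_frac = 0.3) {
  lo <- max(1L, lo); hi <- min(length(env), hi)
  if (lo > hi) return(NA_integer_)
  w <- env[lo:hi]
  k <- which.max(w)
  if (w[k] <= thr) return(NA_integer_)
  if (first) {
    # onset rule: a foot-strike is the *first* appearance of high-frequency
    # content, so take the earliest sample that reaches a substantial
    # fraction of the window maximum; the braking that follows the contact
    # must not postpone the event
    cand <- which(w > thr & w >= rel_frac * w[k])
    if (length(cand)) k <- cand[1]
  }
  lo + k - 1L
}

#' Detect foot-strike and toe-off events
#'
#' Each stationary interval anchors one footfall: the foot-strike is the
#' envelope peak in a window ending at the interval start, the toe-off the
#' peak in a window beginning at the interval end. A peak only counts above
#' `event_k` times the recording's median envelope (a median-relative rule,
#' so detection is invariant to positive rescaling of the input). Intervals
#' lasting at least `standstill_s` are treated as standstills: they separate
#' runs, and a strike detected before one closes the preceding run. The first
#' and last footfall of every run are flagged `is_transition`. Footfalls
#' whose strike has no super-threshold peak are dropped (logged in the
#' `dropped` attribute).
#'
#' @param envelope an `event_envelope` from [wavelet_event_signal()].
#' @param mask a `stationary_mask`.
#' @param cfg a [stairgait_config()].
#' @param side stored in the table (`"left"`, `"right"`, `"unknown"`).
#' @return data.frame of class `gait_events` with columns `stride_id`,
#'   `side`, `run_id`, `t_strike`, `t_off`, `is_transition`.
#' @export
detect_events <- function(envelope, mask, cfg = stairgait_config(),
                          side = "unknown") {
  iv <- mask$intervals
  if (nrow(iv) == 0) stop("need at least one stationary interval", call. = FALSE)
  env <- envelope$env
  t <- envelope$t
  thr <- cfg$event_k * stats::median(env)
  W <- max(1L, round(cfg$event_window_s * envelope$fs))
  n_int <- nrow(iv)
  dur <- t[iv[, 2] - 1L] - t[iv[, 1]]
  is_standstill <- dur >= cfg$standstill_s

  strike_idx <- off_idx <- rep(NA_integer_, n_int)
  for (i in seq_len(n_int)) {
    # clamp the search windows to the half-gap towards the neighbouring
    # stationary interval: the strike lies in the later half of the
    # preceding swing gap, the toe-off in the earlier half of the following
    # one, so the windows never reach into the neighbour's events
    prev_end <- if (i > 1) iv[i - 1, 2] else 1L
    next_start <- if (i < n_int) iv[i + 1, 1] else length(env) + 1L
    lo <- max(iv[i, 1] - W, (prev_end + iv[i, 1]) %/% 2L)
    hi <- min(iv[i, 2] + W - 1L,
              iv[i, 2] + as.integer(ceiling(0.35 * (next_start - iv[i, 2]))))
    strike_idx[i] <- window_peak(env, lo, iv[i, 1] - 1L, thr,
                                 first = TRUE, rel_frac = cfg$event_rel_frac)
    off_idx[i] <- window_peak(env, iv[i, 2], hi, thr)
  }

  has_strike <- !is.na(strike_idx)
  miss <- which(!has_strike & !is_standstill)
  dropped <- data.frame(interval = miss,
                        reason = rep("no super-threshold strike peak",
                                     length(miss)))
  keep <- which(has_strike)
  if (length(keep) == 0) {
    warning("no gait events detected: every stride dropped", call. = FALSE)
    out <- data.frame(stride_id = integer(), side = character(),
                      run_id = integer(), t_strike = numeric(),
                      t_off = numeric(), is_transition = logical())
    class(out) <- c("gait_events", "data.frame")
    attr(out, "dropped") <- dropped
    return(out)
  }
  # run grouping: a standstill interval terminates its run
  run_id <- integer(length(keep))
  current <- 1L
  for (j in seq_along(keep)) {
    run_id[j] <- current
    if (is_standstill[keep[j]]) current <- current + 1L
  }
  out <- data.frame(stride_id = seq_along(keep),
                    side = side,
                    run_id = run_id,
                    t_strike = t[strike_idx[keep]],
                    t_off = t[off_idx[keep]],
                    is_transition = FALSE)
  nt <- max(0L, cfg$n_transition)
  for (r in unique(run_id)) {
    rows <- which(run_id == r)
    if (nt > 0 && length(rows)) {
      head_rows <- rows[seq_len(min(nt, length(rows)))]
      tail_rows <- rows[length(rows) - seq_len(min(nt, length(rows))) + 1L]
      out$is_transition[c(head_rows, tail_rows)] <- TRUE
    }
  }
  if (any(!is.na(out$t_strike)) && is.unsorted(out$t_strike)) {
    stop("detected strikes are not increasing", call. = FALSE)
  }
  class(out) <- c("gait_events", "data.frame")
  attr(out, "dropped") <- dropped
  out
}

#' Stride timing variables
#'
#' Adds to an event table, for each footfall with a successor strike in the
#' same run:
#' \deqn{t_{stride} = \Delta t_{strike}, \quad
#'       t_{stance} = t_{off} - t_{strike}, \quad
#'       t_{swing} = t_{stride} - t_{stance}, \quad
#'       t_{ps} = 100\, t_{stance} / t_{stride}.}
#' The identity \eqn{t_{stance} + t_{swing} = t_{stride}} holds exactly by
#' construction. Under left-right symmetry a `t_ps` above 50% indicates a
#' double-support phase; column `double_support` reports that flag.
#'
#' @param events a `gait_events` table.
#' @return The table with columns `t_stride`, `t_stance`, `t_swing`, `t_ps`,
#'   `double_support` appended.
#' @export
stride_times <- function(events) {
  if (nrow(events) == 0) {
    events$t_stride <- events$t_stance <- events$t_swing <- events$t_ps <-
      numeric(0)
    events$double_support <- logical(0)
    return(events)
  }
  ok <- stats::na.omit(c(events$t_strike, events$t_off))
  if (any(diff(events$t_strike) <= 0, na.rm = TRUE)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  n <- nrow(events)
  nxt <- c(events$t_strike[-1], NA_real_)
  same_run <- c(events$run_id[-1] == events$run_id[-n], FALSE)
  events$t_stride <- ifelse(same_run, nxt - events$t_strike, NA_real_)
  events$t_stance <- events$t_off - events$t_strike
  if (any(events$t_stance <= 0, na.rm = TRUE)) {
    stop("toe-off must follow foot-strike", call. = FALSE)
  }
  events$t_swing <- events$t_stride - events$t_stance
  events$t_ps <- 100 * events$t_stance / events$t_stride
  events$double_support <- events$t_ps > 50
  events
}

#' Export a gait event table to CSV
#' @param events a `gait_events` table.
#' @param path output CSV path.
#' @export
write_events <- function(events, path) {
  cols <- intersect(c("stride_id", "side", "run_id", "t_strike", "t_off",
                      "is_transition"), names(events))
  utils::write.csv(events[, cols], path, row.names = FALSE)
  invisible(path)
}
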