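# Shared fixtures. Simulations are cached per spec so multiple test files can
# reuse the same runs without re-simulating.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(..., side = "left") {
  key <- paste(deparse(list(...)), side, collapse = "")
  key <- digest_key(key)
  if (is.null(.sim_cache[[key]])) {
    spec <- simulation_spec(...)
    .sim_cache[[key]] <- list(spec = spec, sim = simulate_run(spec, side = side))
  }
  .sim_cache[[key]]
}

digest_key <- function(s) {
  # tiny stable hash good enough for a cache key
  paste0("k", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9)
}

cached_run <- function(..., side = "left", cfg = stairgait_config()) {
  entry <- cached_sim(..., side = side)
  key <- paste0(digest_key(paste(deparse(list(...)), side, collapse = "")), "_run")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- suppressWarnings(
      analyze_stair_run(entry$sim$recording, entry$spec$geom, cfg))
  }
  list(spec = entry$spec, sim = entry$sim, run = .sim_cache[[key]])
}

withr_local_tempfile <- function(ext = ".csv") tempfile(fileext = ext)

# still recording fixture: level IMU at rest
still_recording <- function(dur = 2, fs = 128, G = 9.80665) {
  t <- seq(0, dur, by = 1 / fs)
  n <- length(t)
  imu_recording(t, matrix(rep(c(0, 0, G), each = n), ncol = 3),
                matrix(0, n, 3), fs = fs)
}

# stationary mask with intervals of `len_s` every `every_s`
periodic_mask <- function(t, every_s = 0.6, len_s = 0.15, start_s = 0.3) {
  mv <- rep(FALSE, length(t))
  for (s in seq(start_s, max(t) - len_s, by = every_s)) {
    mv[t >= s & t < s + len_s] <- TRUE
  }
  structure(list(mask = mv, intervals = stairgait:::mask_to_intervals(mv),
                 t = t), class = "stationary_mask")
}

steady_truth_metrics <- function(truth) {
  tm <- truth$metrics
  tm[!tm$is_transition & !is.na(tm$t_stride), , drop = FALSE]
}

expect_quat_norm <- function(q, tol = 1e-9) {
  expect_lt(max(abs(sqrt(rowSums(q^2)) - 1)), tol)
}
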