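# Per-stride kinematic and kinetic metrics.

mk_traj <- function(t, pz = NULL, v = NULL) {
  n <- length(t)
  stairgait:::trajectory_series(
    t, matrix(0, n, 3),
    v = if (is.null(v)) matrix(0, n, 3) else v,
    p = cbind(0, 0, if (is.null(pz)) numeric(n) else pz),
    stage = "elevation")
}

test_that("clearance is the elevation difference between the extrema", {
  t <- seq(0, 1, by = 1 / 128)
  pz <- 0.54 + 0.06 * sin(2 * pi * t)   # max 0.60, min 0.48
  traj <- mk_traj(t, pz)
  expect_equal(clearance(traj, 0.25, 0.75), 0.12, tolerance = 1e-3)
  expect_equal(clearance(traj, 0.25, 0.25), 0)
})

test_that("the kinetic-energy proxy squares the mean speed, not the reverse", {
  t <- seq(0, 1, by = 1 / 128)
  n <- length(t)
  const <- mk_traj(t, v = cbind(rep(2, n), 0, 0))
  expect_equal(kinetic_energy_proxy(const, 0, max(t) + 1e-9), 2.0)
  zero <- mk_traj(t, v = matrix(0, n, 3))
  expect_equal(kinetic_energy_proxy(zero, 0, max(t) + 1e-9), 0)

  # sawtooth speed 0 -> 2 -> 0: mean 1 so ke = 0.5 as printed, while the
  # mean-of-squares alternative gives 2/3 — the readings are distinguishable
  sp <- ifelse(t < 0.5, 4 * t, 4 * (1 - t))
  saw <- mk_traj(t, v = cbind(sp, 0, 0))
  expect_equal(kinetic_energy_proxy(saw, 0, max(t) + 1e-9), 0.5,
               tolerance = 0.02)
  expect_equal(kinetic_energy_proxy(saw, 0, max(t) + 1e-9,
                                    mode = "mean-of-squares"),
               2 / 3, tolerance = 0.02)
  expect_error(kinetic_energy_proxy(saw, 5, 6), "empty")
})

test_that("kinetic energy is invariant to a yaw rotation of the trajectory", {
  out <- cached_run(n_strides = 6, seed = 71)
  traj <- out$run$trajectory
  psi <- 0.7
  Rz <- matrix(c(cos(psi), -sin(psi), 0, sin(psi), cos(psi), 0, 0, 0, 1),
               3, byrow = TRUE)
  rot <- traj
  rot$v <- traj$v %*% t(Rz)
  m <- out$run$metrics
  for (i in seq_len(min(3, nrow(m)))) {
    k1 <- kinetic_energy_proxy(traj, m$t_strike[i], m$t_strike[i] + m$t_stride[i])
    k2 <- kinetic_energy_proxy(rot, m$t_strike[i], m$t_strike[i] + m$t_stride[i])
    expect_equal(k1, k2, tolerance = 1e-12)
  }
})

test_that("bounce angles difference the unwrapped pitch and add exactly", {
  t <- seq(0, 1, by = 1 / 128)
  pitch <- approx(c(0, 0.25, 0.5, 1), c(-20, 10, 40, 40) * pi / 180, xout = t)$y
  orient <- stairgait:::orientation_series(
    t, quat_from_euler(0, pitch, 0))
  ang <- bounce_angles(orient, 0, 0.25, 0.5)
  expect_equal(ang$theta_break_deg, 30, tolerance = 1e-6)
  expect_equal(ang$theta_prop_deg, 30, tolerance = 1e-6)
  expect_equal(ang$theta_bounce_deg, 60, tolerance = 1e-6)

  flat <- stairgait:::orientation_series(
    t, quat_from_euler(0, rep(0.2, length(t)), 0))
  a0 <- bounce_angles(flat, 0, 0.3, 0.6)
  expect_equal(a0$theta_bounce_deg, 0)

  expect_error(bounce_angles(orient, 0.6, 0.3, 0.1), "t_strike <= t_min")
})

test_that("the GRF proxy is the net vertical impulse rate over stance", {
  t <- seq(0, 1, by = 1 / 128)
  vz <- approx(c(0, 0.5, 0.8, 1), c(-0.4, -0.4, 0.5, 0.5), xout = t)$y
  traj <- mk_traj(t, v = cbind(0, 0, vz))
  expect_equal(grf_proxy(traj, 0.5, 0.8), 3.0, tolerance = 0.05)
  # momentum-preserving stance: zero force, the descent signature
  sym <- mk_traj(t, v = cbind(0, 0, rep(-0.3, length(t))))
  expect_equal(grf_proxy(sym, 0.2, 0.5), 0)
  expect_error(grf_proxy(traj, 0.5, 0.5), "t_strike < t_off")
})

test_that("extrema location follows the direction-specific rules", {
  out <- cached_run(n_strides = 6, seed = 71)
  tm <- steady_truth_metrics(out$sim$truth)
  em <- out$run$metrics
  expect_equal(nrow(em), nrow(tm))
  expect_lt(max(abs(em$t_min - tm$t_min)), 3.5 / 128)
  expect_lt(max(abs(em$t_max - tm$t_max)), 3.5 / 128)
  # ascent: the apex precedes the strike; the minimum lies inside stance
  expect_true(all(em$t_max < em$t_strike))
  expect_true(all(em$t_min >= em$t_strike - 1 / 128 & em$t_min <= em$t_off))
})

test_that("descent extrema fall inside stance; monotone windows fall back", {
  out <- cached_run(n_strides = 6, seed = 72,
                    geom = stair_geometry(n_treads = 6, direction = "descent"))
  em <- out$run$metrics
  expect_true(all(em$t_max >= em$t_strike - 1 / 128))
  expect_true(all(em$t_max <= em$t_off + 1 / 128))

  # strictly monotone elevation during stance: no local max, fallback flagged
  t <- seq(0, 2, by = 1 / 128)
  pz <- -0.1 * t
  traj <- mk_traj(t, pz)
  ev <- data.frame(stride_id = 1L, side = "left", run_id = 1L,
                   t_strike = 0.5, t_off = 0.9, is_transition = FALSE)
  ev <- stride_times(ev)
  ext <- locate_extrema(traj, ev, "descent")
  expect_true(ext$fallback[1])
  # flat stance elevation: earliest minimizer wins
  pz2 <- rep(1, length(t))
  ext2 <- locate_extrema(mk_traj(t, pz2), ev, "descent")
  expect_equal(ext2$t_min[1], 0.5, tolerance = 1.1 / 128)
})

test_that("assembled metrics keep the bounce identity and protocol counts", {
  left <- cached_run(n_strides = 10, seed = 73, side = "left")
  right <- cached_run(n_strides = 10, seed = 74, side = "right")
  ml <- left$run$metrics; mr <- right$run$metrics
  expect_equal(nrow(ml), 8L)  # 10 footfalls, drop first and last
  expect_equal(nrow(mr), 8L)
  pooled <- pool_metrics(ml, mr)
  expect_equal(nrow(pooled), 16L)
  expect_setequal(unique(pooled$side), c("left", "right"))
  expect_identical(pooled$theta_bounce_deg,
                   pooled$theta_break_deg + pooled$theta_prop_deg)
  expect_true(all(is.finite(as.matrix(
    pooled[, c("t_stride", "t_stance", "t_swing", "t_ps", "clearance_m",
               "ke_m", "theta_bounce_deg", "gf_m")]))))
  expect_true(all(pooled$ke_m >= 0))
})

test_that("ascending runs push off upward: positive gf on average", {
  out <- cached_run(n_strides = 8, seed = 61)
  expect_gt(mean(out$run$metrics$gf_m), 0)
})
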