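# Strapdown integration, ZUPT, footfall ladder, elevation filter.

G <- 9.80665

test_that("gravity cancels exactly for a stationary sensor with exact tilt", {
  rec <- still_recording(dur = 1)
  orient <- integrate_quaternion(c(1, 0, 0, 0), rec$gyro, rec$t)
  traj <- navigation_acceleration(rec, orient)
  expect_lt(max(abs(traj$a_n)), 1e-12)

  # pitched 90 deg: the sensor reads gravity along -y body; still cancels
  q90 <- quat_from_euler(0, pi / 2 * 0.999, 0)
  a_f <- quat_rotate(quat_conjugate(q90), c(0, 0, G))
  rec$accel <- matrix(rep(a_f, each = length(rec$t)), ncol = 3)
  o90 <- stairgait:::orientation_series(rec$t,
                                        matrix(q90, length(rec$t), 4,
                                               byrow = TRUE))
  traj90 <- navigation_acceleration(rec, o90)
  expect_lt(max(abs(traj90$a_n)), 1e-9)
})

test_that("double integration matches elementary kinematics", {
  t <- seq(0, 2, by = 1 / 128)
  n <- length(t)
  a_n <- matrix(0, n, 3); a_n[, 3] <- 1
  traj <- integrate_trajectory(stairgait:::trajectory_series(t, a_n))
  expect_equal(traj$v[n, 3], 2, tolerance = 1e-9)
  expect_equal(traj$p[n, 3], 2, tolerance = 1e-3)  # trapezoid quadrature
  # zero input from rest stays at rest
  tr0 <- integrate_trajectory(stairgait:::trajectory_series(t, a_n * 0),
                              p0 = c(1, 2, 3))
  expect_true(all(tr0$v == 0))
  expect_equal(tr0$p[n, ], c(1, 2, 3))
})

test_that("noise-free simulator trajectory is recovered to the millimetre", {
  entry <- cached_sim(n_strides = 4, seed = 51, gyro_noise_density = 0,
                      accel_noise_density = 0, gyro_bias_deg_s = 0,
                      accel_bias_m_s2 = 0, burst_accel = 0, burst_gyro = 0)
  rec <- entry$sim$recording
  truth <- entry$sim$truth
  orient <- stairgait:::orientation_series(truth$t, truth$q)
  traj <- navigation_acceleration(rec, orient)
  expect_lt(max(abs(traj$a_n - truth$a)), 1e-9)
  traj <- integrate_trajectory(traj)
  one_stride <- truth$t <= truth$events$t_strike[2]
  expect_lt(max(abs(traj$p[one_stride, ] - truth$p[one_stride, ])), 1e-3)
})

test_that("ZUPT removes a constant accelerometer bias exactly at anchors", {
  fs <- 128
  t <- seq(0, 10, by = 1 / fs); n <- length(t)
  a_n <- matrix(0, n, 3); a_n[, 1] <- 0.05
  traj <- integrate_trajectory(stairgait:::trajectory_series(t, a_n))
  mask <- periodic_mask(t, every_s = 1, len_s = 0.2, start_s = 0)
  z <- apply_zupt(traj, mask)
  anchors <- interval_midpoints(mask, t)
  v_anchor <- approx(t, z$v[, 1], xout = anchors)$y
  expect_lt(max(abs(v_anchor)), 1e-6)
  inner <- t >= anchors[1] & t <= anchors[length(anchors)]
  expect_lte(max(abs(z$v[inner, 1])), 0.05 * 1 / 2 + 1e-9)
})

test_that("ZUPT is a no-op on drift-free data and idempotent", {
  t <- seq(0, 6, by = 1 / 128); n <- length(t)
  a_n <- matrix(0, n, 3)
  traj <- integrate_trajectory(stairgait:::trajectory_series(t, a_n))
  mask <- periodic_mask(t, every_s = 1, len_s = 0.2, start_s = 0.5)
  z1 <- apply_zupt(traj, mask)
  expect_lt(max(abs(z1$v - traj$v)), 1e-12)
  z2 <- apply_zupt(z1, mask)
  expect_lt(max(abs(z2$v - z1$v)), 1e-12)
  expect_lt(max(abs(z2$p - z1$p)), 1e-12)

  one <- structure(list(mask = mask$mask,
                        intervals = mask$intervals[1, , drop = FALSE], t = t),
                   class = "stationary_mask")
  expect_error(apply_zupt(traj, one), "at least 2")
})

test_that("ZUPT cuts the stride displacement error of a biased run", {
  entry <- cached_sim(n_strides = 6, seed = 52, gyro_noise_density = 0,
                      accel_noise_density = 0)
  rec <- entry$sim$recording
  truth <- entry$sim$truth
  mask <- detect_stationary(rec)
  orient <- fuse_orientation(rec, mask)
  raw <- integrate_trajectory(navigation_acceleration(rec, orient))
  z <- apply_zupt(raw, mask)
  at <- function(traj, when) traj$p[stairgait:::nearest_index(traj$t, when), 2]
  s <- na.omit(truth$events$t_strike)
  err_raw <- max(abs(diff(sapply(s, at, traj = raw)) - 0.30))
  err_z <- max(abs(diff(sapply(s, at, traj = z)) - 0.30))
  expect_lt(err_z, err_raw / 10)
})

test_that("footfall ladder snaps to treads without skipping", {
  t <- seq(0, 4, by = 1 / 128); n <- length(t)
  mask <- periodic_mask(t, every_s = 1, len_s = 0.25, start_s = 0.25)
  mk_traj <- function(pz_at_anchor) {
    anchors <- interval_midpoints(mask, t)
    pz <- approx(c(0, anchors, max(t)),
                 c(pz_at_anchor[1], pz_at_anchor,
                   pz_at_anchor[length(pz_at_anchor)]), xout = t)$y
    stairgait:::trajectory_series(t, matrix(0, n, 3), v = matrix(0, n, 3),
                                  p = cbind(0, 0, pz), stage = "zupt")
  }
  geom <- stair_geometry(0.18, 0.30, 10, "ascent")
  lad <- build_footfall_ladder(mk_traj(c(0.17, 0.37, 0.53, 0.70)), mask, geom)
  expect_equal(lad$tread[1:3], c(1L, 2L, 3L))
  expect_equal(lad$target_m[1:3], c(0.18, 0.36, 0.54))

  # repeated anchors on the starting tread are allowed (delta n = 0)
  lad0 <- build_footfall_ladder(mk_traj(c(0.01, 0.005, 0.19, 0.37)), mask, geom)
  expect_equal(lad0$tread, c(0L, 0L, 1L, 2L))

  # descent from 8H counts down without skipping
  geom_d <- stair_geometry(0.18, 0.30, 8, "descent")
  lad_d <- build_footfall_ladder(mk_traj(0.18 * c(8, 7, 6, 5)), mask, geom_d)
  expect_equal(lad_d$tread, c(8L, 7L, 6L, 5L))

  # gross drift must trigger the clip warning
  expect_warning(build_footfall_ladder(mk_traj(c(0.0, 0.40, 0.95, 1.55)),
                                       mask, geom), "clip")
})

test_that("elevation filter pulls footfalls onto the riser ladder", {
  entry <- cached_sim(n_strides = 10, seed = 53, gyro_noise_density = 0,
                      accel_noise_density = 0, gyro_bias_deg_s = 0,
                      accel_bias_m_s2 = 0, burst_accel = 0, burst_gyro = 0)
  rec <- entry$sim$recording
  mask <- detect_stationary(rec)
  orient <- fuse_orientation(rec, mask)
  traj <- apply_zupt(integrate_trajectory(navigation_acceleration(rec, orient)),
                     mask)
  # clean trajectory: corrections are tiny, output ~ input
  ladder <- build_footfall_ladder(traj, mask, entry$spec$geom)
  clean <- apply_elevation_filter(traj, ladder)
  expect_lt(max(abs(clean$p[, 3] - traj$p[, 3])), 5e-3)
  # horizontal components are bitwise untouched
  expect_identical(clean$p[, 1:2], traj$p[, 1:2])
  expect_identical(clean$v, traj$v)

  # inject 0.05 m per stride of vertical drift: anchors within 0.02 m of H*n
  drifted <- traj
  drifted$p[, 3] <- drifted$p[, 3] + pmax(0, (traj$t - 2.2)) / 0.6 * 0.05
  lad2 <- suppressWarnings(build_footfall_ladder(drifted, mask,
                                                 entry$spec$geom))
  expect_equal(lad2$tread, 0:10)
  fixed <- apply_elevation_filter(drifted, lad2)
  pz_anchor <- approx(fixed$t, fixed$p[, 3], xout = lad2$time)$y
  expect_lt(max(abs(pz_anchor - lad2$target_m)), 0.02)

  # bookkeeping: total z shift equals the sum of gain-weighted innovations
  upd <- fixed$elev_updates
  expect_equal(fixed$p[length(fixed$t), 3] - drifted$p[length(fixed$t), 3],
               sum(upd$correction), tolerance = 1e-9)
  expect_equal(upd$correction, upd$gain * upd$innov, tolerance = 1e-12)
})

test_that("stage contracts are enforced", {
  t <- seq(0, 1, by = 1 / 128)
  traj <- integrate_trajectory(
    stairgait:::trajectory_series(t, matrix(0, length(t), 3)))
  mask <- periodic_mask(t, every_s = 0.4, len_s = 0.1, start_s = 0.1)
  geom <- stair_geometry()
  expect_error(build_footfall_ladder(traj, mask, geom), "ZUPT")
  expect_error(apply_elevation_filter(traj, NULL), "ZUPT")
})
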