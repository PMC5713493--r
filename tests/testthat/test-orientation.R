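# Quaternion kinematics, accelerometer tilt, and the tilt Kalman filter.

G <- 9.80665

test_that("quaternion integration is exact for constant rotations", {
  t <- seq(0, 1, by = 1 / 128)
  n <- length(t)
  # zero rate: orientation constant
  q0 <- quat_normalize(c(0.9, 0.1, -0.2, 0.3))
  o0 <- integrate_quaternion(q0, matrix(0, n, 3), t)
  expect_equal(o0$q[n, ], q0, tolerance = 1e-12)

  # pi/2 rad/s about z for exactly 1 s: yaw 90 deg, roll = pitch = 0
  o1 <- integrate_quaternion(c(1, 0, 0, 0),
                             matrix(rep(c(0, 0, pi / 2), each = n), ncol = 3), t)
  eul <- o1$euler[n, ]
  expect_equal(eul$yaw, pi / 2, tolerance = 1e-9)
  expect_equal(eul$roll, 0, tolerance = 1e-9)
  expect_equal(eul$pitch, 0, tolerance = 1e-9)
  expect_quat_norm(o1$q)
})

test_that("constant rate about an arbitrary axis matches Rodrigues over 10 s", {
  axis <- c(1, 2, -0.5); axis <- axis / sqrt(sum(axis^2))
  rate <- 1.3
  t <- seq(0, 10, by = 1 / 128)
  gyro <- matrix(rep(axis * rate, each = length(t)), ncol = 3)
  o <- integrate_quaternion(c(1, 0, 0, 0), gyro, t)
  ang <- rate * 10
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, byrow = TRUE)
  R_true <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  R_est <- quat_to_matrix(o$q[nrow(o$q), ])
  expect_lt(norm(R_est - R_true, "F"), 1e-6)
})

test_that("euler <-> quaternion round-trips under the declared convention", {
  set.seed(2)
  for (i in 1:25) {
    roll <- runif(1, -1.2, 1.2); pitch <- runif(1, -1.2, 1.2)
    yaw <- runif(1, -3, 3)
    q <- quat_from_euler(roll, pitch, yaw)
    e <- euler_from_quat(q)
    expect_equal(c(e$roll, e$pitch, e$yaw), c(roll, pitch, yaw),
                 tolerance = 1e-9)
    # the convention ties gravity readings to the tilt formulas
    a_f <- quat_rotate(quat_conjugate(q), c(0, 0, G))
    tl <- accel_tilt(a_f, G)
    expect_equal(tl$roll_a, roll, tolerance = 1e-9)
    expect_equal(tl$pitch_a, pitch, tolerance = 1e-9)
  }
})

test_that("accelerometer tilt follows the closed forms with clamping", {
  level <- accel_tilt(c(0, 0, G), G)
  expect_equal(level$roll_a, 0)
  expect_equal(level$pitch_a, 0)

  t30 <- accel_tilt(c(G / 2, 0, G * sqrt(3) / 2), G)
  expect_equal(t30$roll_a, pi / 6, tolerance = 1e-12)

  gimbal <- accel_tilt(c(G, 0, 0), G)
  expect_equal(gimbal$roll_a, pi / 2, tolerance = 1e-12)
  expect_false(gimbal$valid)
  expect_true(is.na(gimbal$pitch_a))
})

test_that("noise-free fusion tracks the true tilt to a tenth of a degree", {
  entry <- cached_sim(n_strides = 6, seed = 41, gyro_noise_density = 0,
                      accel_noise_density = 0, gyro_bias_deg_s = 0,
                      accel_bias_m_s2 = 0, burst_accel = 0, burst_gyro = 0)
  rec <- entry$sim$recording
  mask <- detect_stationary(rec)
  fo <- fuse_orientation(rec, mask)
  err_deg <- abs(fo$euler$pitch - entry$sim$truth$pitch) * 180 / pi
  expect_lt(max(err_deg), 0.1)
  expect_quat_norm(fo$q)
})

test_that("tilt error stays bounded under gyro bias while open loop drifts", {
  fs <- 128
  t <- seq(0, 60, by = 1 / fs); n <- length(t)
  accel <- matrix(rep(c(0, 0, G), each = n), ncol = 3)
  gyro <- matrix(rep(c(0.5 * pi / 180, 0, 0), each = n), ncol = 3)
  rec <- imu_recording(t, accel, gyro, fs = fs)
  mask <- periodic_mask(t)
  fo <- fuse_orientation(rec, mask)
  open_loop <- integrate_quaternion(c(1, 0, 0, 0), gyro, t)
  filt_err <- max(abs(fo$euler$pitch)) * 180 / pi
  open_err <- abs(open_loop$euler$pitch[n]) * 180 / pi
  expect_lt(filt_err, 2)
  expect_equal(open_err, 30, tolerance = 0.01)  # 0.5 deg/s * 60 s
})

test_that("a wrong initial tilt converges to the accel observation quickly", {
  rec <- still_recording(dur = 4)
  mask <- periodic_mask(rec$t, every_s = 0.5, len_s = 0.2, start_s = 0.2)
  q0 <- quat_from_euler(15 * pi / 180, -20 * pi / 180, 0)
  fo <- fuse_orientation(rec, mask, q0 = q0)
  upd <- fo$updates
  expect_gte(nrow(upd), 5)
  t5 <- upd$t[5]
  after <- fo$t > t5
  expect_lt(max(abs(fo$euler$roll[after])) * 180 / pi, 0.2)
  expect_lt(max(abs(fo$euler$pitch[after])) * 180 / pi, 0.2)
})

test_that("measurement updates never touch yaw", {
  entry <- cached_sim(n_strides = 6, seed = 42)
  rec <- entry$sim$recording
  mask <- detect_stationary(rec)
  fo <- fuse_orientation(rec, mask, stairgait_config())
  upd <- fo$updates
  expect_gt(nrow(upd), 3)
  dyaw <- abs(stairgait:::wrap_angle(upd$yaw_post - upd$yaw_pre))
  expect_lt(max(dyaw), 1e-12)
})

test_that("filter limits: tiny measurement noise pins to the observation,
           huge measurement noise is a no-op", {
  rec <- still_recording(dur = 1.5)
  # tilt the truth: constant accel of a 10-deg pitched sensor
  q_true <- quat_from_euler(0, 10 * pi / 180, 0)
  a_f <- quat_rotate(quat_conjugate(q_true), c(0, 0, G))
  rec$accel <- matrix(rep(a_f, each = length(rec$t)), ncol = 3)
  mask <- periodic_mask(rec$t, every_s = 0.5, len_s = 0.2, start_s = 0.2)
  q0 <- quat_from_euler(0, 0, 0)

  tight <- fuse_orientation(rec, mask,
                            stairgait_config(orient_meas_deg = 1e-4), q0 = q0)
  n <- length(rec$t)
  expect_equal(tight$euler$pitch[n] * 180 / pi, 10, tolerance = 1e-2)

  loose <- fuse_orientation(rec, mask,
                            stairgait_config(orient_meas_deg = 1e5), q0 = q0)
  expect_lt(abs(loose$euler$pitch[n]) * 180 / pi, 1e-3)
})

test_that("zero-length gyro series is rejected", {
  expect_error(integrate_quaternion(c(1, 0, 0, 0),
                                    matrix(0, 0, 3), numeric(0)), "non-empty")
})
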