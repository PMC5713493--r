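# Quaternion algebra and the Euler-angle convention used throughout.
#
# Quaternions are Hamilton quaternions stored as length-4 vectors (or n x 4
# matrices) in (w, x, y, z) order. q maps the IMU (body) frame into the
# navigation frame: v_nav = q o [0, v_body] o q*.
#
# Euler convention (declared once, tested by round-trip): the navigation frame
# is z-up with x lateral and y forward at initialization. Angles are
#   roll  phi   about the forward (y) axis,
#   pitch theta about the lateral (x) axis,
#   yaw   psi   about the vertical (z) axis,
# composed as R = Rz(psi) %*% Ry(-phi) %*% Rx(-theta). The signs are fixed so
# that a stationary accelerometer reads
#   a_f = G * [sin(phi), -cos(phi) sin(theta), cos(phi) cos(theta)],
# which makes the accelerometer tilt equations
#   phi_a = asin(ax / G),  theta_a = -asin(ay / (G cos(phi_a)))
# exact inverses of the orientation parameterization.

#' Normalize quaternions to unit norm
#'
#' @param q length-4 numeric vector or n x 4 matrix (w, x, y, z).
#' @return Same shape as `q`, unit norm.
#' @export
quat_normalize <- function(q) {
  if (is.matrix(q)) {
    q / sqrt(rowSums(q^2))
  } else {
    q / sqrt(sum(q^2))
  }
}

#' Hamilton product of two quaternions
#'
#' @param q1,q2 length-4 numeric vectors (w, x, y, z).
#' @return Length-4 numeric vector `q1 o q2`.
#' @export
quat_multiply <- function(q1, q2) {
  w1 <- q1[1]; x1 <- q1[2]; y1 <- q1[3]; z1 <- q1[4]
  w2 <- q2[1]; x2 <- q2[2]; y2 <- q2[3]; z2 <- q2[4]
  c(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
}

#' Quaternion conjugate
#' @param q length-4 vector or n x 4 matrix.
#' @export
quat_conjugate <- function(q) {
  if (is.matrix(q)) {
    cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
  } else {
    c(q[1], -q[2], -q[3], -q[4])
  }
}

#' Exponential-map quaternion of a rotation-vector increment
#'
#' Closed-form unit quaternion for rotating by `omega * dt` about the body
#' axis `omega / |omega|`.
#' @param omega body angular rate, rad/s (length 3).
#' @param dt time step, s.
#' @return length-4 unit quaternion.
#' @export
quat_exp_rate <- function(omega, dt) {
  ang <- sqrt(sum(omega^2)) * dt
  if (ang < 1e-14) {
    v <- omega * dt / 2
    quat_normalize(c(1, v))
  } else {
    axis <- omega / sqrt(sum(omega^2))
    c(cos(ang / 2), sin(ang / 2) * axis)
  }
}

#' Rotation matrix (body to navigation) of a quaternion
#' @param q length-4 unit quaternion.
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotate 3-vectors from the body frame into the navigation frame
#'
#' Vectorized over rows: `q` may be an n x 4 matrix paired with an n x 3 `v`.
#' @param q length-4 quaternion or n x 4 matrix.
#' @param v length-3 vector or n x 3 matrix.
#' @return Rotated vector(s), same shape as `v`.
#' @export
quat_rotate <- function(q, v) {
  single <- !is.matrix(v)
  if (single) v <- matrix(v, nrow = 1)
  if (!is.matrix(q)) q <- matrix(q, nrow = nrow(v), ncol = 4, byrow = TRUE)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  vx <- v[, 1]; vy <- v[, 2]; vz <- v[, 3]
  # t = 2 q_vec x v ; v' = v + w t + q_vec x t
  tx <- 2 * (y * vz - z * vy)
  ty <- 2 * (z * vx - x * vz)
  tz <- 2 * (x * vy - y * vx)
  out <- cbind(vx + w * tx + (y * tz - z * ty),
               vy + w * ty + (z * tx - x * tz),
               vz + w * tz + (x * ty - y * tx))
  dimnames(out) <- NULL
  if (single) out[1, ] else out
}

#' Quaternion from roll/pitch/yaw under the package convention
#'
#' @param roll,pitch,yaw angles in radians (vectors of equal length).
#' @return n x 4 quaternion matrix (or length-4 vector for scalar input).
#' @export
quat_from_euler <- function(roll, pitch, yaw = 0) {
  n <- max(length(roll), length(pitch), length(yaw))
  roll <- rep_len(roll, n); pitch <- rep_len(pitch, n); yaw <- rep_len(yaw, n)
  cy <- cos(yaw / 2);  sy <- sin(yaw / 2)
  cr <- cos(roll / 2); sr <- sin(roll / 2)
  cp <- cos(pitch / 2); sp <- sin(pitch / 2)
  # q = qz(yaw) o qy(-roll) o qx(-pitch)
  # qz = (cy,0,0,sy); qy = (cr,0,-sr,0); qx = (cp,-sp,0,0)
  # qz o qy = (cy*cr, sy*sr, -cy*sr, sy*cr)
  aw <- cy * cr; ax <- sy * sr; ay <- -cy * sr; az <- sy * cr
  qw <- aw * cp + ax * sp
  qx <- -aw * sp + ax * cp
  qy <- ay * cp - az * sp
  qz <- az * cp + ay * sp
  out <- cbind(qw, qx, qy, qz)
  dimnames(out) <- NULL
  if (n == 1) out[1, ] else out
}

#' Roll/pitch/yaw of quaternions under the package convention
#'
#' @param q length-4 quaternion or n x 4 matrix.
#' @return data.frame with columns `roll`, `pitch`, `yaw` (radians).
#' @export
euler_from_quat <- function(q) {
  if (!is.matrix(q)) q <- matrix(q, nrow = 1)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  r11 <- 1 - 2 * (y^2 + z^2)
  r21 <- 2 * (x * y + w * z)
  r31 <- 2 * (x * z - w * y)
  r32 <- 2 * (y * z + w * x)
  r33 <- 1 - 2 * (x^2 + y^2)
  data.frame(roll = asin(clamp1(r31)),
             pitch = atan2(-r32, r33),
             yaw = atan2(r21, r11))
}
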