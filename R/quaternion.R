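# Hamilton unit-quaternion utilities (scalar-first, sensor -> world
# convention throughout the package).

#' Quaternion product (Hamilton convention)
#'
#' @param a,b Length-4 numeric quaternions, scalar first.
#' @return Length-4 quaternion `a %*% b` in the Hamilton sense.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' @rdname quat_multiply
#' @export
quat_conjugate <- function(a) c(a[1], -a[2], -a[3], -a[4])

#' Normalize a quaternion to unit norm
#' @param a Length-4 quaternion.
#' @return Unit quaternion.
#' @export
quat_normalize <- function(a) {
  n <- sqrt(sum(a^2))
  if (n == 0) stop("cannot normalize a zero quaternion", call. = FALSE)
  a / n
}

#' Rotate a 3-vector by a unit quaternion
#'
#' With the package convention (q: sensor -> world), `quat_rotate(q, v)` maps
#' a sensor-frame vector into the world frame; use `quat_conjugate(q)` for
#' the inverse map.
#'
#' @param q Unit quaternion, scalar first.
#' @param v Length-3 vector.
#' @return Rotated length-3 vector.
#' @export
quat_rotate <- function(q, v) {
  out <- quat_multiply(quat_multiply(q, c(0, v)), quat_conjugate(q))
  out[2:4]
}

#' Rotation matrix of a unit quaternion (sensor -> world)
#' @param q Unit quaternion.
#' @return 3x3 rotation matrix `R` with `R %*% v_sensor = v_world`.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Unit quaternion from a rotation matrix
#' @param R 3x3 rotation matrix (sensor -> world).
#' @return Unit quaternion, scalar part non-negative.
#' @export
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  quat_normalize(q)
}

#' Quaternion from ZYX (yaw-pitch-roll) Euler angles
#' @param yaw,pitch,roll Angles in radians; rotation is
#'   `Rz(yaw) %*% Ry(pitch) %*% Rx(roll)` (sensor -> world).
#' @return Unit quaternion.
#' @export
quat_from_euler <- function(yaw, pitch, roll) {
  cy <- cos(yaw / 2);  sy <- sin(yaw / 2)
  cp <- cos(pitch / 2); sp <- sin(pitch / 2)
  cr <- cos(roll / 2); sr <- sin(roll / 2)
  c(cr * cp * cy + sr * sp * sy,
    sr * cp * cy - cr * sp * sy,
    cr * sp * cy + sr * cp * sy,
    cr * cp * sy - sr * sp * cy)
}

#' Yaw (heading) angle of a unit quaternion, radians
#' @param q Unit quaternion (sensor -> world).
#' @return Yaw in radians, in (-pi, pi].
#' @export
quat_yaw <- function(q) {
  atan2(2 * (q[1] * q[4] + q[2] * q[3]),
        1 - 2 * (q[3]^2 + q[4]^2))
}

#' Angular distance between two unit quaternions
#' @param a,b Unit quaternions.
#' @return Rotation angle in radians needed to take `a` into `b`, in
#'   `[0, pi]` (sign/double-cover insensitive).
#' @export
quat_angle <- function(a, b) {
  d <- abs(sum(a * b))
  2 * acos(min(1, d))
}
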