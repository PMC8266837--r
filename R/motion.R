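# Attitude-and-heading reference system (AHRS) fusion of the transducer
# IMU stream: gradient-descent complementary filter combining gyroscope
# integration with gravity + magnetic-field corrections, in Hamilton
# sensor->world quaternion convention (world z up, gravity (0,0,-9.81)
# m/s^2, magnetic reference horizontal +x).

#' One AHRS update step (gradient-descent complementary filter)
#'
#' Propagates the attitude quaternion by the gyroscope rate and corrects it
#' toward the gravity + magnetic-field reference by a normalized gradient
#' step scaled by `gain` (rad/s worth of correction), then renormalizes.
#' With `gain = 0` the update is pure gyro integration.  A zero-norm
#' accelerometer reading (free fall) skips the correction.
#'
#' @param state List with `q` (unit quaternion sensor -> world) and `t`.
#' @param gyro Length-3 angular rate, rad/s, sensor frame.
#' @param accel Length-3 specific force, m/s^2, sensor frame (gravity
#'   included).
#' @param mag Length-3 magnetic field direction, sensor frame.
#' @param dt Time step, seconds (> 0).
#' @param gain Correction gain (default 0.1).
#' @return Updated state (`q`, `t`).
#' @export
ahrs_update <- function(state, gyro, accel, mag, dt, gain = 0.1) {
  stopifnot(dt > 0)
  q <- state$q
  # exact gyro propagation: right-multiply by the rotation increment
  ang <- sqrt(sum(gyro^2)) * dt
  dq <- if (ang > 0) c(cos(ang / 2), sin(ang / 2) * gyro * dt / ang)
        else c(1, 0, 0, 0)
  q_gyro <- quat_multiply(q, dq)
  # the accel/mag sample is concurrent with the propagated state, so the
  # gradient correction is evaluated there
  w <- q_gyro[1]; x <- q_gyro[2]; y <- q_gyro[3]; z <- q_gyro[4]
  corr <- c(0, 0, 0, 0)

  an <- sqrt(sum(accel^2))
  mn <- sqrt(sum(mag^2))
  if (gain > 0 && an > 0 && mn > 0) {
    a <- accel / an
    m <- mag / mn
    # magnetic reference in world frame from the current estimate:
    # horizontal magnitude + vertical component
    h <- quat_rotate(q_gyro, m)
    bx <- sqrt(h[1]^2 + h[2]^2); bz <- h[3]

    # objective: rotate world references into the sensor frame and compare
    f <- c(2 * (x * z - w * y) - a[1],
           2 * (y * z + w * x) - a[2],
           1 - 2 * (x^2 + y^2) - a[3],
           bx * (1 - 2 * (y^2 + z^2)) + bz * 2 * (x * z - w * y) - m[1],
           bx * 2 * (x * y - w * z) + bz * 2 * (y * z + w * x) - m[2],
           bx * 2 * (x * z + w * y) + bz * (1 - 2 * (x^2 + y^2)) - m[3])
    J <- matrix(c(
      -2 * y,            2 * z,             -2 * w,            2 * x,
       2 * x,            2 * w,              2 * z,            2 * y,
       0,               -4 * x,             -4 * y,            0,
      -2 * bz * y,       2 * bz * z,        -4 * bx * y - 2 * bz * w,
                                            -4 * bx * z + 2 * bz * x,
      -2 * bx * z + 2 * bz * x,  2 * bx * y + 2 * bz * w,
       2 * bx * x + 2 * bz * z, -2 * bx * w + 2 * bz * y,
       2 * bx * y,       2 * bx * z - 4 * bz * x,
       2 * bx * w - 4 * bz * y,  2 * bx * x),
      nrow = 6, byrow = TRUE)
    grad <- as.numeric(crossprod(J, f))
    gn <- sqrt(sum(grad^2))
    if (gn > 0) corr <- -gain * grad / gn
  }
  q <- quat_normalize(q_gyro + corr * dt)
  list(q = q, t = state$t + dt)
}

#' TRIAD-style attitude initialization from one accel/mag sample
#'
#' Builds the initial sensor -> world quaternion from the measured gravity
#' direction (world +z in sensor coordinates) and the horizontal component
#' of the magnetic field (world +x).
#'
#' @param accel Length-3 specific force, sensor frame.
#' @param mag Length-3 magnetic field, sensor frame.
#' @return Unit quaternion sensor -> world.
#' @export
ahrs_init <- function(accel, mag) {
  zs <- accel / sqrt(sum(accel^2))
  xs <- mag - sum(mag * zs) * zs
  nx <- sqrt(sum(xs^2))
  if (nx < 1e-12) stop("magnetic field parallel to gravity", call. = FALSE)
  xs <- xs / nx
  ys <- c(zs[2] * xs[3] - zs[3] * xs[2],
          zs[3] * xs[1] - zs[1] * xs[3],
          zs[1] * xs[2] - zs[2] * xs[1])
  # columns = world axes in sensor coordinates => world -> sensor matrix
  W <- cbind(xs, ys, zs)
  quat_from_matrix(t(W))
}

#' Fuse a full IMU stream into an orientation trajectory
#'
#' Sequential [ahrs_update()] over the stream, initialized TRIAD-style from
#' the first sample.  World-frame linear acceleration is the rotated
#' specific force with the gravity reaction removed:
#' `R(q) a_sensor - (0, 0, 9.81)`.
#'
#' @param imu Data frame with columns `t`, `gx`, `gy`, `gz`, `ax`, `ay`,
#'   `az`, `mx`, `my`, `mz` (at least 2 rows, strictly increasing `t`).
#' @param gain AHRS correction gain (0 = gyro-only integration).
#' @return Data frame `t`, `qw`, `qx`, `qy`, `qz`, `lax`, `lay`, `laz`;
#'   quaternions are unit-norm sensor -> world.
#' @export
fuse_stream <- function(imu, gain = 0.1) {
  n <- nrow(imu)
  if (n < 2) stop("need at least 2 IMU samples", call. = FALSE)
  if (is.unsorted(imu$t, strictly = TRUE))
    stop("IMU timestamps must be strictly increasing", call. = FALSE)
  q <- matrix(NA_real_, n, 4)
  la <- matrix(NA_real_, n, 3)
  ff <- sum(imu$ax == 0 & imu$ay == 0 & imu$az == 0)
  if (ff > 0)
    message(sprintf(
      "fuse_stream: %d free-fall sample(s); gyro-only updates used", ff))
  g_up <- -GRAVITY # accelerometer reads +9.81 up when static
  state <- list(q = ahrs_init(c(imu$ax[1], imu$ay[1], imu$az[1]),
                              c(imu$mx[1], imu$my[1], imu$mz[1])),
                t = imu$t[1])
  q[1, ] <- state$q
  la[1, ] <- quat_rotate(state$q, c(imu$ax[1], imu$ay[1], imu$az[1])) - g_up
  for (i in 2:n) {
    dt <- imu$t[i] - imu$t[i - 1]
    state <- ahrs_update(state,
                         c(imu$gx[i], imu$gy[i], imu$gz[i]),
                         c(imu$ax[i], imu$ay[i], imu$az[i]),
                         c(imu$mx[i], imu$my[i], imu$mz[i]),
                         dt, gain)
    q[i, ] <- state$q
    la[i, ] <- quat_rotate(state$q,
                           c(imu$ax[i], imu$ay[i], imu$az[i])) - g_up
  }
  data.frame(t = imu$t, qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4],
             lax = la[, 1], lay = la[, 2], laz = la[, 3])
}

#' Align an orientation trajectory to video frames
#'
#' Nearest-sample assignment (no interpolation: at 100 Hz IMU vs 30 frames/s
#' the gap is at most 5 ms).  Frames outside the trajectory span by more
#' than `max_gap` are marked missing.
#'
#' @param traj Trajectory from [fuse_stream()].
#' @param frame_times Frame timestamps, seconds.
#' @param max_gap Maximum tolerated distance to the nearest sample, seconds.
#' @return Data frame: `t_frame`, `qw..qz`, `lax..laz`, `matched`.
#' @export
align_motion_to_frames <- function(traj, frame_times, max_gap = 0.05) {
  idx <- findInterval(frame_times, traj$t)
  lo <- pmax(idx, 1)
  hi <- pmin(idx + 1, nrow(traj))
  pick <- ifelse(abs(frame_times - traj$t[lo]) <=
                   abs(traj$t[hi] - frame_times), lo, hi)
  gap <- abs(traj$t[pick] - frame_times)
  ok <- gap <= max_gap
  out <- traj[pick, c("qw", "qx", "qy", "qz", "lax", "lay", "laz")]
  out[!ok, ] <- NA_real_
  cbind(data.frame(t_frame = frame_times), out,
        data.frame(matched = ok, row.names = NULL))
}

#' Event-anchored motion panel
#'
#' Orientation and linear acceleration at 1-s ticks over the window before
#' a machine event (typically a freeze), the standard way to display the
#' approach motion that precedes an acquisition.
#'
#' @param traj Trajectory from [fuse_stream()].
#' @param event_t Anchor event time, seconds.
#' @param before Window length before the event, seconds (default 5).
#' @param step Tick spacing, seconds (default 1).
#' @return Data frame with `t_rel` (seconds relative to the event, ending
#'   at 0) plus the aligned orientation/acceleration columns.
#' @export
motion_event_panel <- function(traj, event_t, before = 5, step = 1) {
  ticks <- seq(event_t - before, event_t, by = step)
  al <- align_motion_to_frames(traj, ticks)
  cbind(data.frame(t_rel = ticks - event_t), al[, -1, drop = FALSE])
}
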