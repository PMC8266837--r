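static_imu <- function(n, rate = 100) {
  data.frame(t = (0:(n - 1)) / rate, gx = 0, gy = 0, gz = 0,
             ax = 0, ay = 0, az = 9.81, mx = 1, my = 0, mz = 0)
}

test_that("identity attitude is an equilibrium of the filter", {
  st <- list(q = c(1, 0, 0, 0), t = 0)
  for (i in 1:100)
    st <- ahrs_update(st, c(0, 0, 0), c(0, 0, 9.81), c(1, 0, 0), 0.01)
  expect_lt(quat_angle(st$q, c(1, 0, 0, 0)), 1e-10)
  expect_lt(abs(sqrt(sum(st$q^2)) - 1), 1e-9)
})

test_that("constant yaw rate integrates to the analytic heading", {
  n <- 101
  t <- (0:(n - 1)) / 100
  yaw <- pi / 2 * t
  imu <- data.frame(t = t, gx = 0, gy = 0, gz = pi / 2,
                    ax = 0, ay = 0, az = 9.81,
                    mx = cos(yaw), my = -sin(yaw), mz = 0)
  traj <- fuse_stream(imu)
  expect_lt(abs(quat_yaw(as.numeric(traj[n, 2:5])) * 180 / pi - 90), 0.5)
})

test_that("static stream yields negligible linear acceleration", {
  cfg <- tiny_config(seed = 51)
  set.seed(51)
  imu <- static_imu(400)
  ns <- cfg$imu_noise
  imu$ax <- imu$ax + stats::rnorm(400, 0, ns[["accel"]])
  imu$ay <- imu$ay + stats::rnorm(400, 0, ns[["accel"]])
  imu$az <- imu$az + stats::rnorm(400, 0, ns[["accel"]])
  traj <- fuse_stream(imu)
  la <- sqrt(traj$lax^2 + traj$lay^2 + traj$laz^2)
  expect_lt(stats::median(la), 3 * ns[["accel"]])
})

test_that("sinusoidal translation recovers the closed-form amplitude", {
  a <- 0.05; f <- 1.2; rate <- 100
  t <- (0:(20 * rate - 1)) / rate
  lin_z <- -a * (2 * pi * f)^2 * sin(2 * pi * f * t)
  imu <- data.frame(t = t, gx = 0, gy = 0, gz = 0,
                    ax = 0, ay = 0, az = 9.81 + lin_z,
                    mx = 1, my = 0, mz = 0)
  traj <- fuse_stream(imu)
  got <- max(abs(traj$laz[t > 2]))
  expect_lt(abs(got - a * (2 * pi * f)^2) / (a * (2 * pi * f)^2), 0.01)
})

test_that("a reversed-and-replayed rotation returns to the start", {
  set.seed(52)
  n <- 300
  gyro <- matrix(stats::rnorm(3 * n, 0, 0.6), n, 3)
  gyro <- rbind(gyro, -gyro[n:1, ])
  q <- c(1, 0, 0, 0)
  qs <- matrix(NA_real_, 2 * n, 4)
  st <- list(q = q, t = 0)
  for (i in seq_len(2 * n)) {
    st <- ahrs_update(st, gyro[i, ], c(0, 0, 0), c(0, 0, 0), 0.01,
                      gain = 0.1) # zero accel: gyro-only branch
    qs[i, ] <- st$q
  }
  expect_lt(quat_angle(st$q, q) * 180 / pi, 1)
  expect_true(all(abs(sqrt(rowSums(qs^2)) - 1) < 1e-9))
})

test_that("zero gain equals pure incremental quaternion integration", {
  set.seed(53)
  n <- 200
  gyro <- matrix(stats::rnorm(3 * n, 0, 0.8), n, 3)
  st <- list(q = c(1, 0, 0, 0), t = 0)
  for (i in seq_len(n))
    st <- ahrs_update(st, gyro[i, ], c(0, 0, 9.81), c(1, 0, 0), 0.01,
                      gain = 0)
  orc <- oracle_gyro_integration(c(1, 0, 0, 0), as.data.frame(gyro), 0.01)
  expect_lt(quat_angle(st$q, orc), 1e-12)
})

test_that("a 30-degree initial error is corrected within 5 s at default gain", {
  st <- list(q = quat_from_euler(30 * pi / 180, 0, 0), t = 0)
  for (i in 1:500)
    st <- ahrs_update(st, c(0, 0, 0), c(0, 0, 9.81), c(1, 0, 0), 0.01)
  expect_lt(quat_angle(st$q, c(1, 0, 0, 0)) * 180 / pi, 1)
})

test_that("orientation is recovered to < 2 degrees RMS on a noisy scan", {
  cfg <- tiny_config(seed = 54)
  set.seed(54)
  im <- simulate_imu(cfg, 40, noise = TRUE)
  traj <- fuse_stream(im$imu)
  expect_true(all(abs(sqrt(traj$qw^2 + traj$qx^2 + traj$qy^2 +
                             traj$qz^2) - 1) < 1e-9))
  idx <- seq(501, nrow(traj)) # skip the 5 s initial convergence
  errs <- vapply(idx, function(i)
    quat_angle(as.numeric(traj[i, c("qw", "qx", "qy", "qz")]),
               im$truth$q[i, ]), numeric(1))
  expect_lt(sqrt(mean(errs^2)) * 180 / pi, 2)
})

test_that("frame alignment is nearest-sample and event panels span 1-s ticks", {
  cfg <- tiny_config(seed = 55)
  set.seed(55)
  im <- simulate_imu(cfg, 12, noise = FALSE)
  traj <- fuse_stream(im$imu)
  al <- align_motion_to_frames(traj, traj$t[c(5, 50, 500)])
  expect_equal(al$qw, traj$qw[c(5, 50, 500)])
  set.seed(56)
  fr <- sort(stats::runif(40, 0, 11.5))
  al2 <- align_motion_to_frames(traj, fr)
  idx <- oracle_nearest(fr, traj$t)
  expect_equal(al2$qw, traj$qw[idx])
  expect_true(all(al2$matched))
  out <- align_motion_to_frames(traj, c(-1, 50))
  expect_false(any(out$matched))
  panel <- motion_event_panel(traj, event_t = 10, before = 5, step = 1)
  expect_equal(nrow(panel), 6)
  expect_equal(panel$t_rel, -5:0)
  expect_true(all(panel$matched))
})

test_that("non-increasing IMU timestamps are rejected", {
  imu <- static_imu(10)
  imu$t[5] <- imu$t[4]
  expect_error(fuse_stream(imu), "increasing")
})
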