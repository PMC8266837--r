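test_that("invalid configurations are rejected with the field named", {
  expect_error(generator_config(duration_bounds = c(50, 40)),
               "duration_bounds")
  expect_error(generator_config(duration_mean = 5), "duration_mean")
  bad_shares <- default_time_shares()
  bad_shares[1] <- bad_shares[1] + 0.1
  expect_error(generator_config(time_shares = bad_shares), "time_shares")
  expect_error(generator_config(pos_weights = c(noun = 0.5, verb = 0.4)),
               "pos_weights")
  expect_error(generator_config(frame_rate = 0), "frame_rate")
})

test_that("degenerate time shares yield a single-label timeline", {
  sh <- stats::setNames(numeric(13), scan_labels())
  sh["thorax_heart"] <- 1
  cfg <- generator_config(seed = 4, time_shares = sh)
  s <- simulate_session(cfg, streams = character(0), duration_min = 5)
  expect_true(all(s$timeline$label == "thorax_heart"))
})

test_that("every timeline partitions [0, duration] exactly", {
  for (seed in 1:25) {
    cfg <- tiny_config(seed)
    s <- simulate_session(cfg, streams = character(0))
    tl <- s$timeline
    expect_true(all(tl$end > tl$start))
    expect_equal(tl$start[-1], tl$end[-nrow(tl)])
    expect_equal(tl$start[1], 0)
    expect_equal(sum(tl$end - tl$start), s$duration, tolerance = 1e-6 / s$duration)
    expect_lt(abs(tl$end[nrow(tl)] - s$duration), 1e-6)
  }
})

test_that("long-run label time fractions converge to the configured shares", {
  cfg <- tiny_config(seed = 20)
  sessions <- simulate_cohort(cfg, 200, streams = character(0))
  tot <- stats::setNames(numeric(13), scan_labels())
  for (s in sessions) {
    d <- tapply(s$timeline$end - s$timeline$start, s$timeline$label, sum)
    tot[names(d)] <- tot[names(d)] + d
  }
  frac <- tot / sum(tot)
  expect_true(all(abs(frac - cfg$time_shares) < 0.01))
})

test_that("sampled durations obey the truncated-normal model", {
  cfg <- tiny_config(seed = 8)
  set.seed(8)
  d <- sample_scan_durations(300, cfg)
  expect_true(all(d >= 10 & d <= 90))
  expect_lt(abs(mean(d) - 36.2), 1.5)
  expect_lt(abs(stats::sd(d) - 11.6), 2.5)
})

test_that("same seed gives byte-identical serialized sessions", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_session(tiny_session(seed = 5, duration_min = 1.5), dir1)
  write_session(tiny_session(seed = 5, duration_min = 1.5), dir2)
  files <- list.files(dir1)
  expect_true(length(files) >= 6)
  for (f in files) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e7),
                     readBin(file.path(dir2, f), "raw", 1e7),
                     label = f)
  }
})

test_that("gaze stream respects screen bounds and timing", {
  s <- tiny_session(seed = 6, duration_min = 2)
  g <- s$gaze
  expect_false(is.unsorted(g$t, strictly = TRUE))
  ok <- g$valid
  expect_true(all(g$x[ok] >= 0 & g$x[ok] < 1920))
  expect_true(all(g$y[ok] >= 0 & g$y[ok] < 1080))
  expect_true(all(is.na(g$x[!ok])))
  expect_gt(mean(!ok), 0)
})

test_that("IMU ground truth is self-consistent", {
  cfg <- tiny_config(seed = 7)
  set.seed(7)
  im <- simulate_imu(cfg, 10, noise = FALSE)
  qn <- sqrt(rowSums(im$truth$q^2))
  expect_true(all(abs(qn - 1) < 1e-9))
  # accelerometer minus rotated gravity reproduces the true linear
  # acceleration exactly in noise-free mode
  for (i in seq(1, nrow(im$imu), by = 97)) {
    a_w <- quat_rotate(im$truth$q[i, ],
                       c(im$imu$ax[i], im$imu$ay[i], im$imu$az[i]))
    expect_lt(max(abs(a_w - c(0, 0, 9.81) - im$truth$linacc[i, ])), 1e-9)
  }
  mn <- sqrt(im$imu$mx^2 + im$imu$my^2 + im$imu$mz^2)
  expect_true(all(abs(mn - 1) < 1e-6))
})

test_that("transcript part-of-speech frequencies obey the law of large numbers", {
  cfg <- tiny_config(seed = 9)
  set.seed(9)
  tr <- simulate_transcript(cfg, n_tokens = 20000)
  st <- corpus_stats(tr, cfg$lexicon)
  expect_true(all(lengths(tr) <= 83))
  for (tag in names(cfg$pos_weights))
    expect_lt(abs(st$pos_fractions[[tag]] - cfg$pos_weights[[tag]]), 0.01)
})

test_that("planted fixations are found iff they exceed the dwell threshold", {
  s <- tiny_session(seed = 10, duration_min = 2)
  s1 <- plant_fixation(s, "bioeffect_box", 30, 150)
  ep <- detect_fixation_episodes(s1$gaze, "bioeffect_box")
  expect_gte(nrow(ep), 1)
  s2 <- plant_fixation(s, "bioeffect_box", 30, 80)
  expect_equal(nrow(detect_fixation_episodes(s2$gaze, "bioeffect_box")), 0)
  expect_error(plant_fixation(s, "bioeffect_box", s$duration - 0.01, 200),
               "outside")
  # k disjoint fixations separated by > 400 ms give exactly k episodes
  s3 <- s
  starts <- c(10, 20, 30, 40, 50)
  for (t0 in starts) s3 <- plant_fixation(s3, "bioeffect_box", t0, 200)
  ep3 <- detect_fixation_episodes(s3$gaze, "bioeffect_box")
  expect_equal(nrow(ep3), length(starts))
  aois <- default_aois()
  orc <- oracle_fixation_episodes(s3$gaze,
                                  aois[aois$name == "bioeffect_box", ])
  expect_equal(ep3$t_start, orc$t_start)
  expect_equal(ep3$t_end, orc$t_end)
})
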