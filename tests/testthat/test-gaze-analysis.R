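box <- data.frame(name = "box", x0 = 0, y0 = 0, x1 = 100, y1 = 100)

stream_inout <- function(t_in1, t_out, t_in2) {
  data.frame(t = c(t_in1, t_out, t_in2),
             x = c(rep(10, length(t_in1)), rep(500, length(t_out)),
                   rep(10, length(t_in2))),
             y = 10, valid = TRUE)
}

test_that("dwell threshold and merge gap boundaries are inclusive", {
  g <- data.frame(t = seq(0, 0.15, by = 0.01), x = 10, y = 10,
                  valid = TRUE)
  ep <- detect_fixation_episodes(g, box)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$n_fixations, 1L)

  # 120 ms fixation, 400 ms interruption, 120 ms fixation -> one episode
  g2 <- stream_inout(seq(0, 0.12, 0.03), seq(0.15, 0.49, 0.02),
                     seq(0.52, 0.64, 0.03))
  ep2 <- detect_fixation_episodes(g2, box)
  expect_equal(nrow(ep2), 1)
  expect_equal(ep2$t_start, 0)
  expect_equal(ep2$t_end, 0.64)
  expect_equal(ep2$n_fixations, 2L)

  # 401 ms interruption -> two episodes
  g3 <- stream_inout(seq(0, 0.12, 0.03), seq(0.15, 0.49, 0.02),
                     seq(0.521, 0.641, 0.03))
  expect_equal(nrow(detect_fixation_episodes(g3, box)), 2)

  # sub-threshold dwells are discarded before merging
  g4 <- data.frame(t = seq(0, 0.08, by = 0.01), x = 10, y = 10,
                   valid = TRUE)
  expect_equal(nrow(detect_fixation_episodes(g4, box)), 0)
  expect_equal(nrow(detect_fixation_episodes(g4[0, ], box)), 0)
})

test_that("detector equals the brute-force run-scan oracle on random streams", {
  set.seed(41)
  for (i in 1:200) {
    g <- random_gaze_stream(sample(10:120, 1), box,
                            p_in = stats::runif(1, 0.2, 0.9))
    ep <- detect_fixation_episodes(g, box)
    orc <- oracle_fixation_episodes(g, box)
    expect_equal(nrow(ep), nrow(orc))
    expect_equal(ep$t_start, orc$t_start)
    expect_equal(ep$t_end, orc$t_end)
    expect_equal(ep$n_fixations, orc$n_fixations)
  }
})

test_that("invalid samples break runs and episodes obey invariants", {
  g <- data.frame(t = seq(0, 0.3, by = 0.02), x = 10, y = 10, valid = TRUE)
  g$valid[8] <- TRUE
  ep_full <- detect_fixation_episodes(g, box)
  g$valid[8] <- FALSE
  ep_cut <- detect_fixation_episodes(g, box, merge_gap = 0.01)
  expect_gt(nrow(ep_cut), nrow(ep_full))
  # episode count monotonically non-increasing in merge_gap
  set.seed(42)
  for (i in 1:20) {
    g <- random_gaze_stream(80, box)
    n_small <- nrow(detect_fixation_episodes(g, box, merge_gap = 0.05))
    n_large <- nrow(detect_fixation_episodes(g, box, merge_gap = 0.8))
    expect_lte(n_large, n_small)
    # and non-increasing in min_fix
    n_lofix <- nrow(detect_fixation_episodes(g, box, min_fix = 0.02))
    n_hifix <- nrow(detect_fixation_episodes(g, box, min_fix = 0.2))
    expect_lte(n_hifix, n_lofix)
  }
  # translation invariance in time
  g$t <- g$t + 1000
  expect_equal(nrow(detect_fixation_episodes(g, box)),
               nrow({ g$t <- g$t - 1000; detect_fixation_episodes(g, box) }))
})

test_that("scan-level AOI flag reflects planted fixations", {
  s <- tiny_session(seed = 43, duration_min = 2)
  expect_false(scan_aoi_flag(s$gaze, "bioeffect_box"))
  expect_true(scan_aoi_flag(plant_fixation(s, "bioeffect_box", 40,
                                           150)$gaze, "bioeffect_box"))
  expect_false(scan_aoi_flag(plant_fixation(s, "bioeffect_box", 40,
                                            80)$gaze, "bioeffect_box"))
})

test_that("measurement gaze rate recovers the planted look fraction", {
  # deterministic extremes
  cfg <- tiny_config(seed = 44, measurement_look_prob = 1)
  s <- simulate_session(cfg, duration_min = 4,
                        measurement_plan = c(HC = 2L, AC = 2L, FL = 2L))
  expect_equal(measurement_gaze_rate(s)$rate, 1)
  cfg0 <- tiny_config(seed = 44, measurement_look_prob = 0)
  s0 <- simulate_session(cfg0, duration_min = 4,
                         measurement_plan = c(HC = 2L, AC = 2L, FL = 2L))
  expect_equal(measurement_gaze_rate(s0)$rate, 0)
  expect_error(measurement_gaze_rate(
    simulate_session(cfg, duration_min = 2,
                     measurement_plan = c(HC = 0L, AC = 0L, FL = 0L))),
    "no measurement events")
  # stochastic plant probability is recovered up to sampling error
  cfg93 <- tiny_config(seed = 45, measurement_look_prob = 0.93)
  sess <- simulate_cohort(cfg93, 25, streams = c("gaze"),
                          duration_min = 4,
                          measurement_plans = rep(list(
                            c(HC = 2L, AC = 2L, FL = 2L)), 25))
  looked <- unlist(lapply(sess, function(s) s$gaze_truth$meas_looked))
  out <- measurement_gaze_rate(sess)
  expect_equal(out$n_events, length(looked))
  expect_equal(out$rate, mean(looked))
  expect_lt(abs(out$rate - 0.93), 0.08)
})

test_that("gaze-to-frame alignment is nearest-timestamp with a gap cutoff", {
  g <- data.frame(t = (0:89) / 30, x = 1:90, y = 1, valid = TRUE)
  al <- align_gaze_to_frames(g, (0:89) / 30)
  expect_true(all(al$matched))
  expect_equal(al$x, g$x)
  # 90 Hz gaze vs 30 fps frames: every frame matched within 5.6 ms
  g2 <- data.frame(t = (0:269) / 90, x = 1, y = 1, valid = TRUE)
  fr <- (0:89) / 30
  al2 <- align_gaze_to_frames(g2, fr)
  expect_true(all(al2$matched))
  set.seed(46)
  g3 <- random_gaze_stream(200, box)
  fr3 <- sort(stats::runif(60, 0, max(g3$t)))
  al3 <- align_gaze_to_frames(g3, fr3)
  idx <- oracle_nearest(fr3, g3$t)
  ok <- abs(g3$t[idx] - fr3) <= 0.05 & g3$valid[idx]
  expect_equal(al3$matched, ok)
  expect_equal(al3$x[ok], g3$x[idx][ok])
})
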