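test_that("temporal regularization removes flicker and fixes smooth input", {
  smooth <- rep(c("spine", "femur"), times = c(90, 120))
  expect_equal(regularize_frame_labels(smooth), smooth)
  flick <- rep("spine", 150)
  flick[70] <- "femur"
  expect_equal(regularize_frame_labels(flick), rep("spine", 150))
  # regularization never invents labels
  set.seed(61)
  noisy <- sample(c("a", "b", "c"), 400, replace = TRUE)
  out <- regularize_frame_labels(noisy, window = 11, min_segment = 0.5)
  expect_length(out, 400)
  expect_true(all(out %in% unique(noisy)))
  # no surviving segment shorter than min_segment
  r <- rle(regularize_frame_labels(noisy, window = 11, min_segment = 1,
                                   frame_rate = 30))
  expect_true(all(r$lengths >= 30) || length(r$lengths) == 1)
})

test_that("mode filtering equals the brute-force windowed-mode oracle", {
  set.seed(62)
  for (i in 1:10) {
    base <- rep(sample(scan_labels(), 4), times = sample(40:80, 4))
    noisy <- base
    flip <- stats::runif(length(base)) < 0.1
    noisy[flip] <- sample(scan_labels(), sum(flip), replace = TRUE)
    expect_equal(regularize_frame_labels(noisy, window = 31,
                                         min_segment = 0),
                 oracle_mode_filter(noisy, 31))
  }
})

test_that("frames -> timeline -> frames is the identity", {
  expect_equal(nrow(timeline_from_frames(rep("spine", 60))), 1)
  alt <- rep(c("a", "b"), 30)
  expect_equal(nrow(timeline_from_frames(alt)), 60)
  set.seed(63)
  for (i in 1:20) {
    labels <- sample(scan_labels(), 200, replace = TRUE,
                     prob = default_time_shares())
    tl <- timeline_from_frames(labels, 30)
    expect_equal(frame_labels_from_timeline(tl, 30, length(labels)),
                 labels)
    expect_equal(tl$start[-1], tl$end[-nrow(tl)])
  }
})

test_that("time shares count frame-exact label durations and sum to one", {
  tl <- data.frame(label = "spine", start = 0, end = 120)
  expect_equal(time_shares(tl), c(spine = 1))
  expect_error(time_shares(data.frame(label = "x", start = 0, end = 0)),
               "zero duration")
  set.seed(64)
  for (i in 1:10) {
    s <- simulate_session(tiny_config(seed = 70 + i),
                          streams = character(0), duration_min = 2)
    sh <- time_shares(s$timeline, scan_labels())
    expect_equal(sum(sh), 1, tolerance = 1e-12)
    # per-frame counting oracle at 1 kHz
    fl <- frame_labels_from_timeline(s$timeline, 1000)
    for (l in names(sh)[sh > 0])
      expect_equal(sh[[l]], mean(fl == l), tolerance = 2e-2)
  }
})

test_that("cohort summary is the textbook t-interval", {
  sh <- matrix(rep(c(0.6, 0.4), each = 4), 4, 2,
               dimnames = list(NULL, c("a", "b")))
  cs <- cohort_summary(sh)
  expect_equal(cs$ci_lo, cs$mean_pct)
  expect_equal(cs$ci_hi, cs$mean_pct)
  x <- c(10.2, 11.5, 9.8, 12.1, 10.9) / 100
  m <- matrix(cbind(x, 1 - x), 5, 2, dimnames = list(NULL, c("a", "b")))
  cs2 <- cohort_summary(m)
  hand_lo <- mean(x) * 100 - stats::qt(0.975, 4) * stats::sd(x) * 100 / sqrt(5)
  expect_equal(cs2$ci_lo[1], hand_lo)
  expect_equal(cs2$mean_pct[1], mean(x) * 100)
  expect_equal(sum(cs2$mean_pct), 100)
  expect_error(cohort_summary(m[1, , drop = FALSE]), "at least 2")
})

test_that("normalized timelines resample to majority-label bins", {
  one <- list(data.frame(label = "spine", start = 0, end = 300))
  m1 <- normalized_timeline_matrix(one, n_bins = 50)
  expect_true(all(m1 == "spine"))
  halves <- list(data.frame(label = c("a", "b"), start = c(0, 150),
                            end = c(150, 300)))
  m2 <- normalized_timeline_matrix(halves, n_bins = 100)
  expect_equal(sum(m2 == "a"), 50)
  expect_equal(sum(m2 == "b"), 50)
  # fine-grained resampling oracle
  set.seed(65)
  s <- simulate_session(tiny_config(seed = 66), streams = character(0),
                        duration_min = 3)
  m3 <- normalized_timeline_matrix(list(s$timeline), n_bins = 20)
  edges <- seq(0, s$duration, length.out = 21)
  fl <- frame_labels_from_timeline(s$timeline, 2000)
  for (b in 1:20) {
    sel <- which((seq_along(fl) - 0.5) / 2000 >= edges[b] &
                   (seq_along(fl) - 0.5) / 2000 < edges[b + 1])
    tab <- table(fl[sel])
    expect_equal(m3[1, b], names(tab)[which.max(tab)])
  }
})

test_that("confusion counts, agreement and invariances are correct", {
  a <- c("x", "x", "y", "z")
  cf <- confusion(a, a)
  expect_equal(cf$agreement, 1)
  expect_true(all(cf$counts[upper.tri(cf$counts)] == 0))
  cf2 <- confusion(a, c("x", "x", "y", "y"))
  expect_equal(cf2$agreement, 0.75)
  expect_equal(sum(cf2$counts), 4)
  rs <- rowSums(cf2$row_normalized[rowSums(cf2$counts) > 0, ])
  expect_true(all(abs(rs - 1) < 1e-12))
  expect_error(confusion(a, a[-1]), "equal length")
  # agreement invariant under a simultaneous label permutation
  perm <- c(x = "z", y = "x", z = "y")
  expect_equal(confusion(perm[a], perm[c("x", "x", "y", "y")])$agreement,
               cf2$agreement)
})

test_that("share correlation matches the closed-form Pearson formula", {
  expect_equal(share_correlation(1:5, 1:5), 1)
  expect_equal(share_correlation(1:5, 5:1), -1)
  x <- c(43, 21, 25, 42, 57); y <- c(99, 65, 79, 75, 87)
  hand <- (sum(x * y) - 5 * mean(x) * mean(y)) /
    sqrt((sum(x^2) - 5 * mean(x)^2) * (sum(y^2) - 5 * mean(y)^2))
  expect_equal(share_correlation(x, y), hand)
  expect_error(share_correlation(rep(1, 4), 1:4), "zero variance")
})

test_that("baseline classifier is exact without noise and ties break lexicographically", {
  cen <- label_centroids(c("b_lab", "a_lab", "c_lab"), 3)
  feats <- cen[c(2, 1, 3, 3), ]
  expect_equal(baseline_classify(feats, cen),
               c("a_lab", "b_lab", "c_lab", "c_lab"))
  mid <- matrix((cen["b_lab", ] + cen["a_lab", ]) / 2, 1)
  expect_equal(baseline_classify(mid, cen), "a_lab")
  expect_error(baseline_classify(matrix(0, 1, 2), cen), "dimensions")
})

test_that("calibrated feature noise hits the target classifier accuracy", {
  k <- 13
  target <- 0.764
  sigma <- calibrate_feature_noise(target, k)
  expect_equal(centroid_channel_accuracy(sigma, k), target,
               tolerance = 1e-6)
  set.seed(67)
  cen <- label_centroids(scan_labels(), 13)
  lab <- sample(scan_labels(), 6000, replace = TRUE)
  feats <- cen[lab, ] + matrix(stats::rnorm(6000 * 13, 0, sigma), 6000, 13)
  acc <- mean(baseline_classify(feats, cen) == lab)
  expect_lt(abs(acc - target), 0.02)
})

test_that("label corruption achieves the requested expected agreement", {
  set.seed(68)
  lab <- sample_clip_labels(8000)
  cor76 <- corrupt_labels(lab, 0.764)
  expect_lt(abs(mean(cor76 == lab) - 0.764), 0.02)
  expect_equal(corrupt_labels(lab, 1), lab)
  expect_true(all(corrupt_labels(lab, 0) != lab))
})
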