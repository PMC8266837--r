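# Seeded synthetic multimodal scan-session generator.  Emulates the
# recording setup of a routine obstetric examination room: a 30 frames/s
# machine UI stream, a 90 Hz screen gaze stream, a 100 Hz transducer IMU,
# a ground-truth anatomy timeline driving all of them, and sonographer
# speech sampled from a tagged lexicon.

GRAVITY <- c(0, 0, -9.81)

# Deterministic per-scan sub-seed, kept inside 32-bit integer range.
scan_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 7919) %% 2147483629)
}

#' Draw scan durations from the truncated-normal duration model
#'
#' Durations are normal with the configured mean and standard deviation
#' (36.2 +/- 11.6 minutes by default) and truncated to `duration_bounds` by
#' resampling.
#'
#' @param n Number of scans.
#' @param config A [generator_config()].
#' @return Numeric vector of durations in minutes.
#' @export
sample_scan_durations <- function(n, config) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rnorm(n, config$duration_mean, config$duration_sd)
    d <- d[d >= config$duration_bounds[1] & d <= config$duration_bounds[2]]
    out <- c(out, d)
  }
  out[seq_len(n)]
}

# Per-label mean dwell time (s): grows with the square root of the label's
# time share, so frequently revisited structures also get longer segments.
label_mean_dwell <- function(config) {
  s <- config$time_shares
  pos <- s > 0
  d <- rep(NA_real_, length(s))
  names(d) <- names(s)
  d[pos] <- config$dwell_base * sqrt(s[pos] / mean(s[pos]))
  d
}

#' Simulate a ground-truth anatomy timeline
#'
#' Semi-Markov construction: segment labels are drawn i.i.d. with
#' probability proportional to `time_shares / mean_dwell` and segment dwell
#' times from a gamma law (shape `dwell_shape`, label-specific mean), so by
#' the renewal-reward theorem the long-run fraction of time in each label
#' equals its configured time share.  Adjacent equal labels are merged; the
#' final segment is truncated at the scan end so segments partition
#' `[0, duration]` exactly.
#'
#' @param config A [generator_config()].
#' @param duration Scan duration in seconds.
#' @return Data frame `label`, `start`, `end` (seconds).
#' @export
simulate_timeline <- function(config, duration) {
  s <- config$time_shares
  d <- label_mean_dwell(config)
  pos <- which(s > 0)
  if (length(pos) == 1) {
    return(data.frame(label = names(s)[pos], start = 0, end = duration,
                      stringsAsFactors = FALSE))
  }
  p <- (s[pos] / d[pos]) / sum(s[pos] / d[pos])
  labels <- character(0); dwells <- numeric(0); total <- 0
  while (total < duration) {
    k <- ceiling((duration - total) / (config$dwell_base / 2)) + 8
    lab <- sample(names(s)[pos], k, replace = TRUE, prob = p)
    dw <- stats::rgamma(k, shape = config$dwell_shape,
                        scale = d[lab] / config$dwell_shape)
    labels <- c(labels, lab); dwells <- c(dwells, dw)
    total <- sum(dwells)
  }
  ends <- cumsum(dwells)
  n <- which(ends >= duration)[1]
  labels <- labels[seq_len(n)]
  ends <- pmin(ends[seq_len(n)], duration)
  starts <- c(0, ends[-n])
  keep <- ends > starts
  tl <- data.frame(label = labels[keep], start = starts[keep],
                   end = ends[keep], stringsAsFactors = FALSE)
  # merge adjacent equal labels
  same <- c(FALSE, tl$label[-1] == tl$label[-nrow(tl)])
  grp <- cumsum(!same)
  data.frame(label = tl$label[!same],
             start = as.numeric(tapply(tl$start, grp, min)),
             end = as.numeric(tapply(tl$end, grp, max)),
             stringsAsFactors = FALSE)
}

meas_value_draw <- function(type) {
  v <- switch(type,
              HC = stats::rnorm(1, 175, 15),
              AC = stats::rnorm(1, 150, 15),
              FL = stats::rnorm(1, 32, 4))
  round(max(v, 1), 1)
}

# Snap a time to the video frame grid.
snap_frame <- function(t, frame_rate) round(t * frame_rate) / frame_rate

#' Simulate ground-truth machine events for a scan
#'
#' Places frozen acquisition intervals (dedicated ones for each planned
#' biometric measurement, plus probabilistic ones at anatomy segment
#' boundaries), save events inside frozen intervals, and measurement
#' displays; all event times are snapped to the video frame grid, so that a
#' lossless UI channel lets the extraction stage recover them exactly.
#'
#' @param config A [generator_config()].
#' @param timeline Timeline from [simulate_timeline()].
#' @param duration Scan duration, seconds.
#' @param measurement_plan Optional override of `config$measurement_plan`.
#' @return List with `events` (truth event data frame: `kind`, `t`, `frame`,
#'   `meas_type`, `meas_value`), `freezes` (`t_on`, `t_off` seconds), and
#'   `ti` (displayed thermal index).
#' @export
simulate_events <- function(config, timeline, duration,
                            measurement_plan = NULL) {
  fr <- config$frame_rate
  if (is.null(measurement_plan)) measurement_plan <- config$measurement_plan
  min_gap <- 1
  iv <- data.frame(t_on = numeric(), t_off = numeric(),
                   meas_type = character(), stringsAsFactors = FALSE)
  overlaps <- function(a, b) any(a < iv$t_off + min_gap &
                                   b > iv$t_on - min_gap)
  # dedicated frozen intervals for planned measurements
  plan <- rep(names(measurement_plan), times = measurement_plan)
  for (ty in plan) {
    len <- min(stats::runif(1, 4, 8), duration / 2)
    for (try in 1:200) {
      t0 <- snap_frame(stats::runif(1, 0, duration - len - 1), fr)
      if (!overlaps(t0, t0 + len)) break
      t0 <- NA
    }
    if (is.na(t0)) next # scan too crowded; plan silently under-filled
    iv <- rbind(iv, data.frame(t_on = t0, t_off = snap_frame(t0 + len, fr),
                               meas_type = ty, stringsAsFactors = FALSE))
  }
  # generic frozen intervals at segment boundaries
  bnd <- timeline$start[-1]
  if (length(bnd) > 0) {
    pick <- bnd[stats::runif(length(bnd)) < config$event_rates[["freeze"]]]
    for (t0 in pick) {
      len <- stats::rgamma(1, 2, scale = config$freeze_mean / 2)
      len <- max(min(len, duration - t0 - 1), 1)
      t0s <- snap_frame(t0, fr)
      if (t0s + len >= duration || overlaps(t0s, t0s + len)) next
      iv <- rbind(iv, data.frame(t_on = t0s,
                                 t_off = snap_frame(t0s + len, fr),
                                 meas_type = NA_character_,
                                 stringsAsFactors = FALSE))
    }
  }
  iv <- iv[order(iv$t_on), , drop = FALSE]
  ev <- new_events()
  for (i in seq_len(nrow(iv))) {
    t_on <- iv$t_on[i]; t_off <- iv$t_off[i]
    ev <- rbind(ev,
                data.frame(kind = c("freeze_on", "freeze_off"),
                           t = c(t_on, t_off),
                           frame = as.integer(round(c(t_on, t_off) * fr)),
                           meas_type = NA_character_, meas_value = NA_real_,
                           stringsAsFactors = FALSE))
    u <- stats::runif(2)
    if (u[1] < config$event_rates[["image_save"]]) {
      ts <- snap_frame(stats::runif(1, t_on + 0.5, t_off - 1 / fr), fr)
      ev <- rbind(ev, data.frame(kind = "image_save", t = ts,
                                 frame = as.integer(round(ts * fr)),
                                 meas_type = NA_character_,
                                 meas_value = NA_real_,
                                 stringsAsFactors = FALSE))
    }
    if (u[2] < config$event_rates[["clip_save"]]) {
      ts <- snap_frame(stats::runif(1, t_on + 0.5, t_off - 1 / fr), fr)
      ev <- rbind(ev, data.frame(kind = "clip_save", t = ts,
                                 frame = as.integer(round(ts * fr)),
                                 meas_type = NA_character_,
                                 meas_value = NA_real_,
                                 stringsAsFactors = FALSE))
    }
    if (!is.na(iv$meas_type[i])) {
      tm <- snap_frame(t_on + 1, fr)
      ev <- rbind(ev, data.frame(kind = "measurement_display", t = tm,
                                 frame = as.integer(round(tm * fr)),
                                 meas_type = iv$meas_type[i],
                                 meas_value = meas_value_draw(iv$meas_type[i]),
                                 stringsAsFactors = FALSE))
    }
  }
  ev <- ev[order(ev$t, ev$frame), , drop = FALSE]
  rownames(ev) <- NULL
  list(events = ev, freezes = iv[, c("t_on", "t_off")],
       ti = round(stats::runif(1, 0.2, 0.7), 1))
}

#' Materialize the per-frame UI stream of a scan
#'
#' Expands truth events into one structured UI state record per video frame:
#' frozen flag over frozen intervals, save kind on event frames, the active
#' measurement display (from one second after its freeze onset until the
#' freeze ends), and the constant thermal index.
#'
#' @param config A [generator_config()].
#' @param duration Scan duration, seconds.
#' @param ev Result of [simulate_events()].
#' @return Data frame `frame`, `t`, `frozen`, `save`, `meas_type`,
#'   `meas_value`, `ti`.
#' @export
build_ui_frames <- function(config, duration, ev) {
  fr <- config$frame_rate
  n <- floor(duration * fr)
  frame <- 0:(n - 1)
  t <- frame / fr
  frozen <- rep(FALSE, n)
  save <- rep("none", n)
  mt <- rep(NA_character_, n)
  mv <- rep(NA_real_, n)
  fz <- ev$freezes
  for (i in seq_len(nrow(fz))) {
    f0 <- round(fz$t_on[i] * fr); f1 <- round(fz$t_off[i] * fr)
    frozen[frame >= f0 & frame < f1] <- TRUE
  }
  e <- ev$events
  sv <- e[e$kind %in% c("image_save", "clip_save"), , drop = FALSE]
  save[match(sv$frame, frame)] <- sv$kind
  me <- e[e$kind == "measurement_display", , drop = FALSE]
  for (i in seq_len(nrow(me))) {
    f0 <- me$frame[i]
    f_off <- e$frame[e$kind == "freeze_off" & e$frame > f0]
    f1 <- if (length(f_off) > 0) min(f_off) else n
    sel <- frame >= f0 & frame < f1
    mt[sel] <- me$meas_type[i]
    mv[sel] <- me$meas_value[i]
  }
  data.frame(frame = frame, t = t, frozen = frozen, save = save,
             meas_type = mt, meas_value = mv, ti = ev$ti,
             stringsAsFactors = FALSE)
}

#' Simulate the screen gaze stream of a scan
#'
#' Gaze is an isotropic Gaussian cloud around the current attractor: the
#' live image centre by default, the measurement box around displayed
#' measurements the synthetic sonographer chooses to read
#' (`measurement_look_prob`), and, in a `bioeffect_look_prob` fraction of
#' scans, one brief visit to the thermal-safety box.  A `gaze_dropout`
#' fraction of samples is invalid.
#'
#' @param config A [generator_config()].
#' @param duration Scan duration, seconds.
#' @param events Truth event data frame (may be `NULL` for a plain stream).
#' @param aois AOI table.
#' @return List with `gaze` (data frame `t`, `x`, `y`, `valid`),
#'   `meas_looked` (logical per measurement event), `bioeffect_planted`.
#' @export
simulate_gaze <- function(config, duration, events = NULL,
                          aois = default_aois()) {
  n <- floor(duration * config$gaze_rate)
  t <- (0:(n - 1)) / config$gaze_rate
  img <- aoi_rect(aois, "image_area")
  cx <- (img$x0 + img$x1) / 2; cy <- (img$y0 + img$y1) / 2
  x <- cx + stats::rnorm(n, 0, config$gaze_sigma)
  y <- cy + stats::rnorm(n, 0, config$gaze_sigma)

  place <- function(x, y, sel, rect) {
    m <- sum(sel)
    bx <- (rect$x0 + rect$x1) / 2; by <- (rect$y0 + rect$y1) / 2
    x[sel] <- pmin(pmax(bx + stats::rnorm(m, 0, 5), rect$x0 + 1),
                   rect$x1 - 1)
    y[sel] <- pmin(pmax(by + stats::rnorm(m, 0, 5), rect$y0 + 1),
                   rect$y1 - 1)
    list(x = x, y = y)
  }

  meas_looked <- logical(0)
  if (!is.null(events)) {
    me <- events[events$kind == "measurement_display", , drop = FALSE]
    meas_looked <- stats::runif(nrow(me)) < config$measurement_look_prob
    mb <- aoi_rect(aois, "measurement_box")
    for (i in seq_len(nrow(me))) {
      if (!meas_looked[i]) next
      sel <- t >= me$t[i] - 0.3 & t <= me$t[i] + 1.2
      p <- place(x, y, sel, mb); x <- p$x; y <- p$y
    }
  }
  bioeffect <- stats::runif(1) < config$bioeffect_look_prob
  if (bioeffect && duration > 12) {
    t0 <- stats::runif(1, 5, duration - 6)
    sel <- t >= t0 & t <= t0 + 0.4
    p <- place(x, y, sel, aoi_rect(aois, "bioeffect_box"))
    x <- p$x; y <- p$y
  }
  valid <- stats::runif(n) >= config$gaze_dropout
  x <- pmin(pmax(x, 0), config$screen[1] - 1e-6)
  y <- pmin(pmax(y, 0), config$screen[2] - 1e-6)
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  list(gaze = data.frame(t = t, x = x, y = y, valid = valid),
       meas_looked = meas_looked, bioeffect_planted = bioeffect)
}

#' Simulate the transducer IMU stream from a scripted trajectory
#'
#' Ground truth is a smooth sensor-to-world orientation built from
#' sinusoidal roll/pitch/yaw (random phases per scan) plus a sinusoidal
#' translation; body rates follow from exact Euler-angle kinematics, the
#' accelerometer reads the world-frame specific force (linear acceleration
#' minus gravity) rotated into the sensor frame, and the magnetometer reads
#' the horizontal world +x reference.  Sensor noise is added per
#' `config$imu_noise` unless `noise = FALSE`; the magnetometer output is
#' re-normalized to unit length.
#'
#' @param config A [generator_config()].
#' @param duration Stream duration, seconds.
#' @param noise Add sensor noise?
#' @return List with `imu` (data frame `t`, `gx..gz`, `ax..az`, `mx..mz`)
#'   and `truth` (`q`: n x 4 unit quaternions sensor -> world, `linacc`:
#'   n x 3 world-frame linear acceleration).
#' @export
simulate_imu <- function(config, duration, noise = TRUE) {
  n <- floor(duration * config$imu_rate)
  t <- (0:(n - 1)) / config$imu_rate
  ph <- stats::runif(6, 0, 2 * pi)
  A <- c(roll = 0.5, pitch = 0.35, yaw = 0.9)
  f <- c(roll = 0.20, pitch = 0.13, yaw = 0.045)
  ang <- function(nm, k) A[[nm]] * sin(2 * pi * f[[nm]] * t + ph[k])
  dang <- function(nm, k) A[[nm]] * 2 * pi * f[[nm]] *
    cos(2 * pi * f[[nm]] * t + ph[k])
  roll <- ang("roll", 1); pitch <- ang("pitch", 2); yaw <- ang("yaw", 3)
  droll <- dang("roll", 1); dpitch <- dang("pitch", 2); dyaw <- dang("yaw", 3)

  # body rates from ZYX Euler kinematics
  gx <- droll - dyaw * sin(pitch)
  gy <- dpitch * cos(roll) + dyaw * cos(pitch) * sin(roll)
  gz <- -dpitch * sin(roll) + dyaw * cos(pitch) * cos(roll)

  # translation: p_i(t) = amp_i sin(2 pi fp_i t + phase)
  amp <- c(0.02, 0.02, 0.01); fp <- c(0.9, 0.7, 1.1)
  lin <- sapply(1:3, function(i)
    -amp[i] * (2 * pi * fp[i])^2 * sin(2 * pi * fp[i] * t + ph[3 + i]))

  # rotation matrix elements (sensor -> world), vectorized over samples
  cr <- cos(roll); sr <- sin(roll); cp <- cos(pitch); sp <- sin(pitch)
  cy <- cos(yaw); sy <- sin(yaw)
  R11 <- cy * cp; R12 <- cy * sp * sr - sy * cr; R13 <- cy * sp * cr + sy * sr
  R21 <- sy * cp; R22 <- sy * sp * sr + cy * cr; R23 <- sy * sp * cr - cy * sr
  R31 <- -sp;     R32 <- cp * sr;                R33 <- cp * cr

  rot_w2s <- function(vx, vy, vz)
    cbind(R11 * vx + R21 * vy + R31 * vz,
          R12 * vx + R22 * vy + R32 * vz,
          R13 * vx + R23 * vy + R33 * vz)
  spec <- rot_w2s(lin[, 1] - GRAVITY[1], lin[, 2] - GRAVITY[2],
                  lin[, 3] - GRAVITY[3])
  mag <- rot_w2s(rep(1, n), rep(0, n), rep(0, n))

  # quaternion truth (scalar-first), elementwise ZYX composition
  hr <- roll / 2; hp <- pitch / 2; hy <- yaw / 2
  q <- cbind(cos(hr) * cos(hp) * cos(hy) + sin(hr) * sin(hp) * sin(hy),
             sin(hr) * cos(hp) * cos(hy) - cos(hr) * sin(hp) * sin(hy),
             cos(hr) * sin(hp) * cos(hy) + sin(hr) * cos(hp) * sin(hy),
             cos(hr) * cos(hp) * sin(hy) - sin(hr) * sin(hp) * cos(hy))

  if (noise) {
    ns <- config$imu_noise
    gx <- gx + stats::rnorm(n, 0, ns[["gyro"]])
    gy <- gy + stats::rnorm(n, 0, ns[["gyro"]])
    gz <- gz + stats::rnorm(n, 0, ns[["gyro"]])
    spec <- spec + matrix(stats::rnorm(3 * n, 0, ns[["accel"]]), n, 3)
    mag <- mag + matrix(stats::rnorm(3 * n, 0, ns[["mag"]]), n, 3)
  }
  mag <- mag / sqrt(rowSums(mag^2))
  list(imu = data.frame(t = t, gx = gx, gy = gy, gz = gz,
                        ax = spec[, 1], ay = spec[, 2], az = spec[, 3],
                        mx = mag[, 1], my = mag[, 2], mz = mag[, 3]),
       truth = list(q = q, linacc = lin))
}

#' Simulate a sonographer speech transcript
#'
#' Sentence lengths follow a capped negative-binomial law; each token's
#' part of speech is drawn from `pos_weights` and the word uniformly from
#' the lexicon entries carrying that tag.
#'
#' @param config A [generator_config()].
#' @param duration_min Scan duration in minutes (sets the expected token
#'   count via `words_per_min`).
#' @param n_tokens Optional explicit token budget overriding the duration.
#' @return List of sentences, each a character vector of lowercase words.
#' @export
simulate_transcript <- function(config, duration_min = NULL,
                                n_tokens = NULL) {
  if (is.null(n_tokens)) {
    stopifnot(!is.null(duration_min))
    n_tokens <- stats::rpois(1, config$words_per_min * duration_min)
  }
  lex <- split(config$lexicon$word, config$lexicon$tag)
  pw <- config$pos_weights
  sentences <- list()
  used <- 0
  while (used < n_tokens) {
    len <- min(1 + stats::rnbinom(1, size = 2, mu = 8), 83,
               n_tokens - used)
    if (len < 1) break
    tags <- sample(names(pw), len, replace = TRUE, prob = pw)
    words <- vapply(tags, function(tg) {
      pool <- lex[[tg]]
      pool[sample.int(length(pool), 1)]
    }, character(1), USE.NAMES = FALSE)
    sentences[[length(sentences) + 1]] <- words
    used <- used + len
  }
  sentences
}

#' Label centroids for the baseline clip classifier
#'
#' One-hot unit vectors, one per label, in a `dim`-dimensional feature
#' space (labels beyond `dim` wrap, which never happens with defaults).
#'
#' @param label_set Character label vector.
#' @param dim Feature dimension.
#' @return Matrix labels x dim with row names.
#' @export
label_centroids <- function(label_set, dim = length(label_set)) {
  m <- matrix(0, length(label_set), dim,
              dimnames = list(label_set, NULL))
  for (i in seq_along(label_set)) m[i, ((i - 1) %% dim) + 1] <- 1
  m
}

timeline_label_at <- function(timeline, t) {
  i <- findInterval(t, timeline$start)
  i <- pmin(pmax(i, 1), nrow(timeline))
  timeline$label[i]
}

simulate_clip_features <- function(config, events, timeline) {
  qual <- events[events$kind %in% c("freeze_on", "image_save", "clip_save"),
                 , drop = FALSE]
  lab <- timeline_label_at(timeline, qual$t)
  cen <- label_centroids(config$label_set, config$feature_dim)
  feat <- cen[lab, , drop = FALSE] +
    matrix(stats::rnorm(nrow(qual) * config$feature_dim, 0,
                        config$feature_noise_sd),
           nrow(qual), config$feature_dim)
  out <- data.frame(t = qual$t, kind = qual$kind, label = lab,
                    stringsAsFactors = FALSE)
  colnames(feat) <- paste0("f", seq_len(ncol(feat)))
  cbind(out, as.data.frame(feat))
}

#' Simulate one complete synthetic scan session
#'
#' Draws the scan duration, the ground-truth anatomy timeline and machine
#' events, then materializes the requested modality streams.  Fully
#' reproducible from `config$seed` (the global RNG state is set at entry).
#'
#' @param config A [generator_config()].
#' @param scan_id Identifier recorded in the session.
#' @param streams Subset of
#'   `c("ui", "gaze", "imu", "transcript", "clips")` to materialize; the
#'   timeline and truth events are always generated.
#' @param duration_min Optional fixed duration in minutes (skips the
#'   duration model).
#' @param measurement_plan Optional per-scan HC/AC/FL display counts
#'   overriding the config.
#' @param imu_noise Add IMU sensor noise?
#' @return Object of class `"scan_session"`: a list with `scan_id`,
#'   `duration` (seconds), `timeline`, `events`, `freezes`, and the
#'   requested `ui`, `gaze`, `imu`, `imu_truth`, `transcript`,
#'   `clip_features` plus `gaze_truth` bookkeeping.
#' @export
simulate_session <- function(config, scan_id = "scan_001",
                             streams = c("ui", "gaze", "imu", "transcript",
                                         "clips"),
                             duration_min = NULL,
                             measurement_plan = NULL,
                             imu_noise = TRUE) {
  validate_config(config)
  set.seed(config$seed)
  dur_min <- if (is.null(duration_min)) sample_scan_durations(1, config)
             else duration_min
  duration <- round(dur_min * 60, 3)
  timeline <- simulate_timeline(config, duration)
  ev <- simulate_events(config, timeline, duration, measurement_plan)
  s <- list(scan_id = scan_id, config = config, duration = duration,
            timeline = timeline, events = ev$events, freezes = ev$freezes,
            ti = ev$ti)
  if ("ui" %in% streams) s$ui <- build_ui_frames(config, duration, ev)
  if ("gaze" %in% streams) {
    g <- simulate_gaze(config, duration, ev$events)
    s$gaze <- g$gaze
    s$gaze_truth <- list(meas_looked = g$meas_looked,
                         bioeffect_planted = g$bioeffect_planted)
  }
  if ("imu" %in% streams) {
    im <- simulate_imu(config, duration, noise = imu_noise)
    s$imu <- im$imu
    s$imu_truth <- im$truth
  }
  if ("transcript" %in% streams)
    s$transcript <- simulate_transcript(config, duration / 60)
  if ("clips" %in% streams)
    s$clip_features <- simulate_clip_features(config, ev$events, timeline)
  class(s) <- "scan_session"
  s
}

#' @export
print.scan_session <- function(x, ...) {
  cat(sprintf("<scan_session %s> %.1f min, %d timeline segments, %d events\n",
              x$scan_id, x$duration / 60, nrow(x$timeline), nrow(x$events)))
  invisible(x)
}

#' Simulate a cohort of scan sessions
#'
#' Each scan uses a deterministic per-scan sub-seed derived from
#' `config$seed`, so any cohort prefix is reproducible independently of the
#' cohort size.
#'
#' @inheritParams simulate_session
#' @param n Number of scans.
#' @param measurement_plans Optional list (length `n`) of per-scan HC/AC/FL
#'   count overrides.
#' @return List of `scan_session` objects.
#' @export
simulate_cohort <- function(config, n,
                            streams = c("ui", "gaze", "imu", "transcript",
                                        "clips"),
                            duration_min = NULL,
                            measurement_plans = NULL) {
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- scan_seed(config$seed, i)
    simulate_session(cfg, sprintf("scan_%04d", i), streams = streams,
                     duration_min = duration_min,
                     measurement_plan = measurement_plans[[i]])
  })
}

#' Plant a gaze fixation into a session (test fixture)
#'
#' Relocates every gaze sample falling in `[t_start, t_start + dwell_ms]`
#' to the centre of the named AOI and marks it valid; all other samples are
#' untouched.  Used to build sessions with known fixation ground truth.
#'
#' @param session A `scan_session` with a gaze stream.
#' @param aoi_name AOI name resolved against `aois`.
#' @param t_start Start of the planted dwell, seconds.
#' @param dwell_ms Dwell duration in milliseconds.
#' @param aois AOI table.
#' @return The modified session.
#' @export
plant_fixation <- function(session, aoi_name, t_start, dwell_ms,
                           aois = default_aois()) {
  rect <- aoi_rect(aois, aoi_name)
  t_end <- t_start + dwell_ms / 1000
  if (t_start < 0 || t_end > session$duration)
    stop("fixation interval outside the scan", call. = FALSE)
  g <- session$gaze
  sel <- g$t >= t_start & g$t <= t_end
  g$x[sel] <- (rect$x0 + rect$x1) / 2
  g$y[sel] <- (rect$y0 + rect$y1) / 2
  g$valid[sel] <- TRUE
  session$gaze <- g
  session
}
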