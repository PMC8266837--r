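# Independent brute-force oracles used to check the vectorized
# implementations.  Deliberately written as plain loops over samples.

oracle_fixation_episodes <- function(gaze, rect, min_fix = 0.1,
                                     merge_gap = 0.4) {
  runs <- list()
  cur <- NULL
  for (i in seq_len(nrow(gaze))) {
    ins <- isTRUE(gaze$valid[i]) && !is.na(gaze$x[i]) && !is.na(gaze$y[i]) &&
      gaze$x[i] >= rect$x0 && gaze$x[i] < rect$x1 &&
      gaze$y[i] >= rect$y0 && gaze$y[i] < rect$y1
    if (ins) {
      if (is.null(cur)) cur <- c(gaze$t[i], gaze$t[i])
      else cur[2] <- gaze$t[i]
    } else if (!is.null(cur)) {
      runs[[length(runs) + 1]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
  fix <- Filter(function(r) (r[2] - r[1]) >= min_fix, runs)
  if (length(fix) == 0)
    return(data.frame(t_start = numeric(), t_end = numeric(),
                      n_fixations = integer()))
  eps <- list(c(fix[[1]], 1))
  if (length(fix) > 1) {
    for (k in 2:length(fix)) {
      last <- eps[[length(eps)]]
      if (fix[[k]][1] - last[2] <= merge_gap) {
        last[2] <- fix[[k]][2]
        last[3] <- last[3] + 1
        eps[[length(eps)]] <- last
      } else {
        eps[[length(eps) + 1]] <- c(fix[[k]], 1)
      }
    }
  }
  data.frame(t_start = vapply(eps, `[`, numeric(1), 1),
             t_end = vapply(eps, `[`, numeric(1), 2),
             n_fixations = as.integer(vapply(eps, `[`, numeric(1), 3)))
}

oracle_freeze_events <- function(frozen, frame, frame_rate = 30) {
  kinds <- character(0); at <- integer(0)
  for (i in seq_along(frozen)[-1]) {
    if (frozen[i] && !frozen[i - 1]) { kinds <- c(kinds, "freeze_on"); at <- c(at, i) }
    if (!frozen[i] && frozen[i - 1]) { kinds <- c(kinds, "freeze_off"); at <- c(at, i) }
  }
  data.frame(kind = kinds, t = frame[at] / frame_rate,
             frame = as.integer(frame[at]), stringsAsFactors = FALSE)
}

oracle_extract_clips <- function(events, duration, clip_len = 5) {
  q <- events[events$kind %in% c("freeze_on", "image_save", "clip_save"), ]
  q <- q[order(q$t), ]
  kept <- list()
  for (i in seq_len(nrow(q))) {
    e <- min(q$t[i], duration)
    s <- max(0, e - clip_len)
    if (e <= s) next
    drop <- FALSE
    for (k in kept) {
      ov <- max(0, min(k[2], e) - max(k[1], s))
      if (ov >= 0.5 * (e - s)) { drop <- TRUE; break }
    }
    if (!drop) kept[[length(kept) + 1]] <- c(s, e)
  }
  if (length(kept) == 0)
    return(data.frame(t_start = numeric(), t_end = numeric()))
  data.frame(t_start = vapply(kept, `[`, numeric(1), 1),
             t_end = vapply(kept, `[`, numeric(1), 2))
}

# per-frame majority label of a clip window, sampled at 1 kHz
oracle_clip_label <- function(t_start, t_end, timeline) {
  ts <- seq(t_start + 5e-4, t_end - 5e-4, by = 1e-3)
  lab <- character(length(ts))
  for (i in seq_along(ts)) {
    for (k in seq_len(nrow(timeline))) {
      if (ts[i] >= timeline$start[k] && ts[i] < timeline$end[k]) {
        lab[i] <- timeline$label[k]
        break
      }
    }
  }
  tab <- table(lab[lab != ""])
  names(tab)[which.max(tab)]
}

oracle_mode_filter <- function(labels, window) {
  n <- length(labels)
  half <- window %/% 2
  out <- character(n)
  prev <- labels[1]
  for (i in seq_len(n)) {
    win <- labels[max(1, i - half):min(n, i + half)]
    counts <- sapply(unique(win), function(l) sum(win == l))
    best <- names(counts)[counts == max(counts)]
    out[i] <- if (length(best) == 1) best else
      if (prev %in% best) prev else best[1]
    prev <- out[i]
  }
  out
}

oracle_nearest <- function(query, ref) {
  vapply(query, function(q) which.min(abs(ref - q)), integer(1))
}

# pure incremental quaternion integration of a gyro stream
oracle_gyro_integration <- function(q0, gyro, dt) {
  q <- q0
  for (i in seq_len(nrow(gyro))) {
    w <- as.numeric(gyro[i, ])
    ang <- sqrt(sum(w^2)) * dt
    dq <- if (ang > 0) c(cos(ang / 2), sin(ang / 2) * w * dt / ang)
          else c(1, 0, 0, 0)
    q <- quat_multiply(q, dq)
    q <- q / sqrt(sum(q^2))
  }
  q
}

random_gaze_stream <- function(n, rect, p_in = 0.5, rate = 90,
                               p_invalid = 0.05) {
  t <- cumsum(stats::rexp(n, rate))
  ins <- stats::runif(n) < p_in
  x <- ifelse(ins, stats::runif(n, rect$x0, rect$x1 - 1e-9),
              rect$x1 + stats::runif(n, 1, 100))
  y <- ifelse(ins, stats::runif(n, rect$y0, rect$y1 - 1e-9),
              rect$y0 + stats::runif(n, 0, rect$y1 - rect$y0))
  valid <- stats::runif(n) > p_invalid
  data.frame(t = t, x = x, y = y, valid = valid)
}
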