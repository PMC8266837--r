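# Fixation-episode detection over screen areas of interest, and the two
# gaze audits built on it (thermal-safety box, biometric measurement box).

#' Detect fixation episodes toward one area of interest
#'
#' A *fixation* is a maximal run of consecutive in-AOI gaze samples whose
#' duration (first to last in-AOI timestamp, making the rule independent of
#' sampling rate) is at least `min_fix` seconds.  Consecutive fixations
#' separated by an interruption of at most `merge_gap` seconds are merged
#' into a single *episode*; longer interruptions split episodes.  Both
#' thresholds are inclusive.  Invalid or missing samples count as
#' outside-AOI and therefore break runs.
#'
#' @param gaze Data frame with columns `t` (seconds, strictly increasing),
#'   `x`, `y` (pixels, origin top-left), `valid` (logical).
#' @param aoi Single-row data frame (see [default_aois()]) or an AOI name to
#'   be resolved against `aois`.
#' @param min_fix Minimum fixation duration, seconds (default 0.1).
#' @param merge_gap Maximum interruption merged into one episode, seconds
#'   (default 0.4).
#' @param aois AOI table used when `aoi` is given by name.
#' @return Data frame with columns `aoi`, `t_start`, `t_end`, `n_fixations`,
#'   sorted and non-overlapping; zero rows when no episode is found.
#' @export
detect_fixation_episodes <- function(gaze, aoi, min_fix = 0.1,
                                     merge_gap = 0.4,
                                     aois = default_aois()) {
  if (is.character(aoi)) aoi <- aoi_rect(aois, aoi)
  empty <- data.frame(aoi = character(), t_start = numeric(),
                      t_end = numeric(), n_fixations = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(gaze) == 0) return(empty)
  if (is.unsorted(gaze$t, strictly = TRUE))
    stop("gaze timestamps must be strictly increasing", call. = FALSE)

  inside <- in_aoi(gaze$x, gaze$y, gaze$valid, aoi)
  if (!any(inside)) return(empty)

  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  run_start_t <- gaze$t[starts[r$values]]
  run_end_t <- gaze$t[ends[r$values]]
  keep <- (run_end_t - run_start_t) >= min_fix
  if (!any(keep)) return(empty)
  fs <- run_start_t[keep]
  fe <- run_end_t[keep]

  # merge fixations whose gap to the previous fixation is <= merge_gap
  n <- length(fs)
  new_episode <- c(TRUE, (fs[-1] - fe[-n]) > merge_gap)
  ep <- cumsum(new_episode)
  data.frame(aoi = aoi$name,
             t_start = tapply(fs, ep, min),
             t_end = tapply(fe, ep, max),
             n_fixations = as.integer(tapply(fs, ep, length)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Was an AOI looked at during a scan?
#'
#' @inheritParams detect_fixation_episodes
#' @return `TRUE` iff at least one fixation episode toward the AOI exists.
#' @export
scan_aoi_flag <- function(gaze, aoi, min_fix = 0.1, merge_gap = 0.4,
                          aois = default_aois()) {
  nrow(detect_fixation_episodes(gaze, aoi, min_fix, merge_gap, aois)) > 0
}

#' Fraction of biometric measurements accompanied by a measurement-box gaze
#'
#' For every `measurement_display` event, checks whether a fixation episode
#' toward the measurement box overlaps the window `[t - window, t + window]`
#' around the event.  The audit quantifies how often sonographers look at the
#' machine-displayed value while measuring, the behaviour underlying
#' expected-value bias in biometry.
#'
#' @param sessions A single session (list with `gaze` and `events`) or a list
#'   of such sessions.  `events` must contain `kind`, `t` and, for
#'   measurement events, `meas_type`.
#' @param window Half-width of the overlap window around each measurement
#'   event, seconds.
#' @param aois AOI table; the `"measurement_box"` entry is used.
#' @inheritParams detect_fixation_episodes
#' @return List with `rate` (overall fraction in `[0, 1]`), `by_type`
#'   (named per-measurement-type fractions), and `n_events`.
#' @export
measurement_gaze_rate <- function(sessions, window = 2, min_fix = 0.1,
                                  merge_gap = 0.4, aois = default_aois()) {
  if (!is.null(sessions$gaze)) sessions <- list(sessions)
  hit <- character(0); type <- character(0)
  for (s in sessions) {
    ev <- s$events
    me <- ev[ev$kind == "measurement_display", , drop = FALSE]
    if (nrow(me) == 0) next
    ep <- detect_fixation_episodes(s$gaze, "measurement_box",
                                   min_fix, merge_gap, aois)
    for (i in seq_len(nrow(me))) {
      lo <- me$t[i] - window
      hi <- me$t[i] + window
      ok <- nrow(ep) > 0 && any(ep$t_start <= hi & ep$t_end >= lo)
      hit <- c(hit, if (ok) "yes" else "no")
      type <- c(type, me$meas_type[i])
    }
  }
  if (length(hit) == 0)
    stop("no measurement events in the supplied sessions", call. = FALSE)
  by_type <- tapply(hit == "yes", type, mean)
  list(rate = mean(hit == "yes"),
       by_type = stats::setNames(as.numeric(by_type), names(by_type)),
       n_events = length(hit))
}

#' Assign the nearest gaze sample to each video frame
#'
#' Nearest-timestamp matching; a frame is marked missing when the nearest
#' sample is invalid or farther than `max_gap` seconds away.
#'
#' @param gaze Gaze data frame (`t`, `x`, `y`, `valid`).
#' @param frame_times Numeric vector of frame timestamps, seconds.
#' @param max_gap Maximum tolerated time distance, seconds (default 0.05).
#' @return Data frame with one row per frame: `t_frame`, `x`, `y`, `matched`.
#' @export
align_gaze_to_frames <- function(gaze, frame_times, max_gap = 0.05) {
  if (nrow(gaze) == 0 || length(frame_times) == 0)
    stop("both gaze stream and frame timestamps must be non-empty",
         call. = FALSE)
  idx <- findInterval(frame_times, gaze$t)
  lo <- pmax(idx, 1)
  hi <- pmin(idx + 1, nrow(gaze))
  pick <- ifelse(abs(frame_times - gaze$t[lo]) <=
                   abs(gaze$t[hi] - frame_times), lo, hi)
  gap <- abs(gaze$t[pick] - frame_times)
  ok <- gap <= max_gap & gaze$valid[pick]
  data.frame(t_frame = frame_times,
             x = ifelse(ok, gaze$x[pick], NA_real_),
             y = ifelse(ok, gaze$y[pick], NA_real_),
             matched = ok)
}
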