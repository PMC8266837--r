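#' Anatomy label set for routine second-trimester scan workflow analysis
#'
#' The 12 most common anatomy/standard-plane labels used to annotate 5-s scan
#' clips, plus a residual `"other"` category that absorbs everything else.
#' Order is fixed and shared by [default_time_shares()] and
#' [default_clip_prevalence()].
#'
#' @return Character vector of 13 label names.
#' @export
scan_labels <- function() {
  c("thorax_heart", "head_brain", "mode_3d4d", "unidentified", "spine",
    "abdomen", "maternal_anatomy", "coronal_face", "placenta_amniotic_fluid",
    "sagittal_face", "kidneys", "femur", "other")
}

#' Reference per-label share of scan time
#'
#' Expected fraction of a routine second-trimester scan's duration dedicated
#' to each anatomy label, as reported for large scan cohorts (cardiac imaging
#' dominating at around 21.5%, head and brain around 11.4%).  Used as the
#' generator's default semi-Markov stationary distribution.  The raw reported
#' percentages are normalized to sum exactly to 1.
#'
#' @return Named numeric vector over [scan_labels()] summing to 1.
#' @export
default_time_shares <- function() {
  pct <- c(21.5, 11.4, 3.1, 17.7, 8.8, 5.9, 10.5, 4.1, 4.3, 5.2, 1.6, 3.0, 3.1)
  stats::setNames(pct / sum(pct), scan_labels())
}

#' Reference prevalence of anatomy labels among 5-s clips
#'
#' Fraction of event-anchored 5-s clips carrying each of the 12 most common
#' anatomy labels in manually annotated scan libraries; the 12 named labels
#' cover roughly 88% of clips and the remainder is pooled into `"other"`.
#'
#' @param as_fraction Return fractions summing to 1 (default) instead of the
#'   raw percentages.
#' @return Named numeric vector over [scan_labels()].
#' @export
default_clip_prevalence <- function(as_fraction = TRUE) {
  pct <- c(19.6, 11.5, 11.2, 11.0, 6.1, 5.5, 5.5, 4.4, 4.2, 3.3, 2.9, 2.7)
  pct <- c(pct, 100 - sum(pct))
  out <- stats::setNames(pct, scan_labels())
  if (as_fraction) out / sum(out) else out
}

#' Default part-of-speech sampling weights for sonographer speech
#'
#' Token-level distribution over coarse part-of-speech classes typical of
#' spoken scan commentary: adjectives 12.7%, determiners 22.2%, nouns 28.0%,
#' verbs 16.0%, and 21.1% other (prepositions, pronouns, adverbs, ...).
#'
#' @return Named numeric vector summing to 1.
#' @export
default_pos_weights <- function() {
  c(adjective = 0.127, determiner = 0.222, noun = 0.280, verb = 0.160,
    other = 0.211)
}

#' Build a validated synthetic scan-session generator configuration
#'
#' Collects every tunable of the multimodal session generator: acquisition
#' rates, the truncated-normal scan-duration model, the semi-Markov anatomy
#' timeline (label set, stationary time shares, gamma dwell times), machine
#' event rates at segment boundaries, the per-scan biometric measurement plan,
#' gaze behaviour, IMU noise, and the tagged speech lexicon.
#'
#' @param seed Integer seed; every stream of the session is reproducible from
#'   it.
#' @param frame_rate Video/UI frame rate in frames per second.
#' @param gaze_rate Eye-tracker sampling rate in samples per second.
#' @param imu_rate Inertial sensor sampling rate in samples per second.
#' @param duration_mean,duration_sd Scan duration model, minutes.
#' @param duration_bounds Length-2 truncation bounds in minutes; draws outside
#'   are resampled.
#' @param label_set Ordered anatomy label vector (12 common labels +
#'   `"other"`).
#' @param time_shares Named expected fraction of scan time per label, summing
#'   to 1.
#' @param dwell_shape Gamma shape of segment dwell times.
#' @param dwell_base Baseline mean segment dwell in seconds; per-label mean
#'   dwell scales with the square root of the label's time share.
#' @param event_rates Named list/vector: `freeze` = probability that a segment
#'   boundary starts a frozen acquisition; `image_save`, `clip_save` =
#'   conditional probabilities of a save during a frozen interval.
#' @param freeze_mean Mean duration of a frozen interval, seconds.
#' @param measurement_plan Named integer counts of HC/AC/FL measurement
#'   displays per scan.
#' @param measurement_look_prob Probability the synthetic sonographer fixates
#'   the measurement box around a displayed measurement.
#' @param bioeffect_look_prob Probability a scan contains at least one
#'   fixation on the thermal-safety ("bioeffect") box.
#' @param gaze_sigma Isotropic gaze noise around the current attractor,
#'   pixels.
#' @param gaze_dropout Fraction of invalid (dropped) gaze samples.
#' @param imu_noise Named vector of sensor noise standard deviations:
#'   `gyro` (rad/s), `accel` (m/s^2), `mag` (unitless, applied before
#'   re-normalization).
#' @param pos_weights Named part-of-speech sampling weights for transcripts.
#' @param lexicon Data frame with columns `word`, `tag` covering every
#'   part-of-speech class in `pos_weights`.
#' @param words_per_min Expected spoken words per scan minute.
#' @param screen Screen size in pixels, `c(width, height)`.
#' @param feature_dim Dimension of per-clip feature vectors (stand-in for
#'   video content consumed by the baseline clip classifier).
#' @param feature_noise_sd Isotropic noise of clip features around their
#'   label centroid (centroids are unit-separated one-hot vectors).
#'
#' @return Object of class `"generator_config"` (a validated list).
#' @seealso [simulate_session()], [simulate_cohort()]
#' @export
generator_config <- function(seed = 1L,
                             frame_rate = 30,
                             gaze_rate = 90,
                             imu_rate = 100,
                             duration_mean = 36.2,
                             duration_sd = 11.6,
                             duration_bounds = c(10, 90),
                             label_set = scan_labels(),
                             time_shares = default_time_shares(),
                             dwell_shape = 2,
                             dwell_base = 20,
                             event_rates = c(freeze = 0.5, image_save = 0.7,
                                             clip_save = 0.08),
                             freeze_mean = 8,
                             measurement_plan = c(HC = 1L, AC = 2L, FL = 1L),
                             measurement_look_prob = 0.93,
                             bioeffect_look_prob = 27 / 637,
                             gaze_sigma = 15,
                             gaze_dropout = 0.02,
                             imu_noise = c(gyro = 0.005, accel = 0.05,
                                           mag = 0.01),
                             pos_weights = default_pos_weights(),
                             lexicon = build_lexicon(),
                             words_per_min = 12,
                             screen = c(1920, 1080),
                             feature_dim = length(label_set),
                             feature_noise_sd = 0.35) {
  cfg <- list(seed = as.integer(seed), frame_rate = frame_rate,
              gaze_rate = gaze_rate, imu_rate = imu_rate,
              duration_mean = duration_mean, duration_sd = duration_sd,
              duration_bounds = duration_bounds, label_set = label_set,
              time_shares = time_shares, dwell_shape = dwell_shape,
              dwell_base = dwell_base, event_rates = event_rates,
              freeze_mean = freeze_mean,
              measurement_plan = measurement_plan,
              measurement_look_prob = measurement_look_prob,
              bioeffect_look_prob = bioeffect_look_prob,
              gaze_sigma = gaze_sigma, gaze_dropout = gaze_dropout,
              imu_noise = imu_noise, pos_weights = pos_weights,
              lexicon = lexicon, words_per_min = words_per_min,
              screen = screen, feature_dim = feature_dim,
              feature_noise_sd = feature_noise_sd)
  class(cfg) <- "generator_config"
  validate_config(cfg)
  cfg
}

config_error <- function(field, msg) {
  stop(sprintf("invalid generator configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

#' Validate a generator configuration
#'
#' Checks every structural invariant of a [generator_config()]; errors name
#' the offending field.
#'
#' @param cfg A `generator_config` object.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    config_error("seed", "must be a single integer")
  for (f in c("frame_rate", "gaze_rate", "imu_rate", "duration_mean",
              "duration_sd", "dwell_shape", "dwell_base", "freeze_mean",
              "words_per_min"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      config_error(f, "must be a single strictly positive number")
  b <- cfg$duration_bounds
  if (length(b) != 2 || b[1] >= b[2])
    config_error("duration_bounds", "must be an increasing length-2 vector")
  if (cfg$duration_mean <= b[1] || cfg$duration_mean >= b[2])
    config_error("duration_mean", "must lie strictly inside duration_bounds")
  ts <- cfg$time_shares
  if (is.null(names(ts)) || !setequal(names(ts), cfg$label_set))
    config_error("time_shares", "must be named by label_set")
  if (any(ts < 0)) config_error("time_shares", "must be non-negative")
  if (abs(sum(ts) - 1) > 1e-9) config_error("time_shares", "must sum to 1")
  pw <- cfg$pos_weights
  if (abs(sum(pw) - 1) > 1e-9) config_error("pos_weights", "must sum to 1")
  if (any(pw < 0)) config_error("pos_weights", "must be non-negative")
  er <- cfg$event_rates
  if (!all(c("freeze", "image_save", "clip_save") %in% names(er)))
    config_error("event_rates", "must name freeze, image_save, clip_save")
  if (any(er <= 0) || any(er > 1))
    config_error("event_rates", "must be probabilities in (0, 1]")
  mp <- cfg$measurement_plan
  if (!all(c("HC", "AC", "FL") %in% names(mp)) || any(mp < 0))
    config_error("measurement_plan", "must give non-negative HC/AC/FL counts")
  for (f in c("measurement_look_prob", "bioeffect_look_prob", "gaze_dropout"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      config_error(f, "must be a probability in [0, 1]")
  if (!all(c("gyro", "accel", "mag") %in% names(cfg$imu_noise)) ||
      any(cfg$imu_noise < 0))
    config_error("imu_noise", "must give non-negative gyro/accel/mag sds")
  lx <- cfg$lexicon
  if (!is.data.frame(lx) || !all(c("word", "tag") %in% names(lx)))
    config_error("lexicon", "must be a data frame with columns word, tag")
  if (!all(names(pw) %in% unique(lx$tag)))
    config_error("lexicon", "must cover every part-of-speech class")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  seed: %d | rates: %g fps video, %g Hz gaze, %g Hz IMU\n",
              x$seed, x$frame_rate, x$gaze_rate, x$imu_rate))
  cat(sprintf("  duration: %.1f +/- %.1f min, truncated to [%g, %g]\n",
              x$duration_mean, x$duration_sd,
              x$duration_bounds[1], x$duration_bounds[2]))
  cat(sprintf("  labels: %d (top share %s = %.1f%%)\n", length(x$label_set),
              names(which.max(x$time_shares)), 100 * max(x$time_shares)))
  invisible(x)
}

# Split an exact total into n non-negative integer parts that sum to it,
# as evenly as possible (remainder spread over the first cells).
allocate_counts <- function(total, n) {
  base <- total %/% n
  rem <- total %% n
  counts <- rep.int(base, n)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  counts
}
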