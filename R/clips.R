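# Event-anchored 5-second clip partitioning: one clip per important
# machine event (freeze, image save, clip save), window ending at the
# event, near-duplicate windows dropped.

QUALIFYING_EVENTS <- c("freeze_on", "image_save", "clip_save")

#' Extract 5-second clips around important machine events
#'
#' Each qualifying event (freeze on, image save, clip save) anchors one clip
#' spanning `[max(0, t - clip_len), t]`: the approach context preceding the
#' event, since sonographers freeze or save once satisfied with the
#' acquisition on screen.  A clip whose window overlaps an earlier kept
#' clip's window by at least half of its own length is dropped, so a freeze
#' followed immediately by a save does not double-count one acquisition.
#'
#' @param events Events data frame (from [extract_event_timeline()] or the
#'   generator truth), sorted by `t`.
#' @param scan_duration Scan duration, seconds.
#' @param clip_len Clip length, seconds (default 5).
#' @param scan_id Identifier copied into the clips.
#' @return Data frame `clip_id`, `scan_id`, `t_start`, `t_end`, `anchor`
#'   (event kind), `anchor_t`, sorted by `t_start`.
#' @export
extract_clips <- function(events, scan_duration, clip_len = 5,
                          scan_id = "scan") {
  stopifnot(scan_duration > 0)
  q <- events[events$kind %in% QUALIFYING_EVENTS, , drop = FALSE]
  q <- q[order(q$t), , drop = FALSE]
  empty <- data.frame(clip_id = character(), scan_id = character(),
                      t_start = numeric(), t_end = numeric(),
                      anchor = character(), anchor_t = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(q) == 0) return(empty)
  t_end <- pmin(q$t, scan_duration)
  t_start <- pmax(0, t_end - clip_len)
  keep <- logical(nrow(q))
  ks <- numeric(0); ke <- numeric(0)
  for (i in seq_len(nrow(q))) {
    len <- t_end[i] - t_start[i]
    if (len <= 0) next
    ov <- if (length(ks) == 0) 0 else
      max(pmax(0, pmin(ke, t_end[i]) - pmax(ks, t_start[i])))
    if (ov < 0.5 * len) {
      keep[i] <- TRUE
      ks <- c(ks, t_start[i]); ke <- c(ke, t_end[i])
    }
  }
  out <- data.frame(scan_id = scan_id, t_start = t_start[keep],
                    t_end = t_end[keep], anchor = q$kind[keep],
                    anchor_t = q$t[keep], stringsAsFactors = FALSE)
  out <- out[order(out$t_start), , drop = FALSE]
  out <- cbind(clip_id = sprintf("%s_clip_%04d", scan_id,
                                 seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Assign ground-truth anatomy labels to clips by majority time overlap
#'
#' Each clip receives the timeline label with the largest time overlap with
#' its window; exact ties go to the later segment's label.
#'
#' @param clips Clips data frame from [extract_clips()].
#' @param timeline Timeline data frame (`label`, `start`, `end`).
#' @return `clips` with a `label` column appended.
#' @export
assign_truth_label <- function(clips, timeline) {
  lab <- character(nrow(clips))
  for (i in seq_len(nrow(clips))) {
    ov <- pmax(0, pmin(timeline$end, clips$t_end[i]) -
                 pmax(timeline$start, clips$t_start[i]))
    by_lab <- tapply(ov, timeline$label, sum)
    best <- max(by_lab)
    cand <- names(by_lab)[by_lab >= best - 1e-12]
    if (length(cand) == 1) {
      lab[i] <- cand
    } else {
      # tie: prefer the label whose latest overlapping segment is later
      latest <- vapply(cand, function(l)
        max(timeline$start[timeline$label == l & ov > 0]), numeric(1))
      lab[i] <- cand[which.max(latest)]
    }
  }
  clips$label <- lab
  clips
}

#' Per-label fraction of clips
#'
#' @param clips Clips data frame with a `label` column, or a bare character
#'   vector of labels.
#' @return Named numeric fractions over observed labels, summing to 1.
#' @export
clip_prevalence <- function(clips) {
  labels <- if (is.character(clips)) clips else clips$label
  if (length(labels) == 0) stop("no clips to summarize", call. = FALSE)
  tab <- table(labels)
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  out
}

#' Sample clip labels from a prevalence distribution
#'
#' Convenience sampler used to emulate large annotated clip libraries.
#'
#' @param n Number of clip labels.
#' @param prevalence Named non-negative weights (need not sum to 1).
#' @return Character vector of length `n`.
#' @export
sample_clip_labels <- function(n, prevalence = default_clip_prevalence()) {
  sample(names(prevalence), n, replace = TRUE, prob = prevalence)
}

#' Attach generator clip features to extracted clips
#'
#' Joins each clip to the generator's per-event feature vector by anchor
#' time (exact match on the frame-snapped event time).
#'
#' @param clips Clips data frame from [extract_clips()].
#' @param session A `scan_session` with `clip_features`.
#' @return `clips` with feature columns `f1..fd` appended; clips without a
#'   matching generator event get `NA` features.
#' @export
attach_clip_features <- function(clips, session) {
  cf <- session$clip_features
  idx <- vapply(seq_len(nrow(clips)), function(i) {
    j <- which(abs(cf$t - clips$anchor_t[i]) < 1e-6 &
                 cf$kind == clips$anchor[i])
    if (length(j) >= 1) j[1] else NA_integer_
  }, integer(1))
  fcols <- grep("^f\\d+$", names(cf), value = TRUE)
  cbind(clips, cf[idx, fcols, drop = FALSE])
}
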