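# Workflow statistics: frame-label regularization, timelines, per-scan and
# cohort time shares, normalized timeline matrices, confusion/agreement
# analysis, and the nearest-centroid baseline clip classifier.

#' Temporally regularize a per-frame label sequence
#'
#' Sliding-window mode filter (ties keep the previous output label) followed
#' by absorption of segments shorter than `min_segment` seconds into their
#' longer neighbour.  Output length equals input length and no label absent
#' from the input window is ever introduced.
#'
#' @param labels Character vector of per-frame labels at a fixed frame rate.
#' @param window Mode-filter window in frames (odd; default 31).
#' @param min_segment Minimum surviving segment duration, seconds (0
#'   disables the merge pass).
#' @param frame_rate Frames per second.
#' @return Character vector of regularized labels, same length.
#' @export
regularize_frame_labels <- function(labels, window = 31, min_segment = 1,
                                    frame_rate = 30) {
  n <- length(labels)
  if (n == 0) return(labels)
  half <- window %/% 2
  out <- character(n)
  prev <- labels[1]
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    tab <- table(labels[lo:hi])
    best <- names(tab)[tab == max(tab)]
    out[i] <- if (length(best) == 1) best[1]
              else if (prev %in% best) prev else best[1]
    prev <- out[i]
  }
  min_frames <- round(min_segment * frame_rate)
  if (min_frames > 1) {
    repeat {
      r <- rle(out)
      if (length(r$lengths) <= 1 || all(r$lengths >= min_frames)) break
      k <- which(r$lengths < min_frames)
      k <- k[which.min(r$lengths[k])][1]
      left <- if (k > 1) r$lengths[k - 1] else -1
      right <- if (k < length(r$lengths)) r$lengths[k + 1] else -1
      r$values[k] <- if (right >= left) r$values[k + 1] else r$values[k - 1]
      out <- inverse.rle(r)
      # re-run rle so adjacent equal labels merge before the next pass
    }
  }
  out
}

#' Run-length encode per-frame labels into a timeline
#'
#' @param labels Per-frame label vector.
#' @param frame_rate Frames per second.
#' @return Timeline data frame `label`, `start`, `end`; segment `i` covers
#'   frames at `[start, end)` with `end` of the last segment equal to
#'   `n / frame_rate`.
#' @export
timeline_from_frames <- function(labels, frame_rate = 30) {
  stopifnot(length(labels) > 0)
  r <- rle(labels)
  ends <- cumsum(r$lengths) / frame_rate
  data.frame(label = r$values, start = c(0, ends[-length(ends)]),
             end = ends, stringsAsFactors = FALSE)
}

#' Sample a timeline back to per-frame labels
#'
#' Inverse of [timeline_from_frames()]: the label of frame `k` is the
#' timeline label at time `(k + 0.5) / frame_rate`.
#'
#' @param timeline Timeline data frame.
#' @param frame_rate Frames per second.
#' @param n_frames Number of frames (default: full timeline span).
#' @return Character vector of per-frame labels.
#' @export
frame_labels_from_timeline <- function(timeline, frame_rate = 30,
                                       n_frames = NULL) {
  if (is.null(n_frames))
    n_frames <- round(max(timeline$end) * frame_rate)
  t_mid <- (seq_len(n_frames) - 0.5) / frame_rate
  timeline_label_at(timeline, t_mid)
}

#' Per-label fraction of scan time
#'
#' @param timeline Timeline data frame (`label`, `start`, `end`).
#' @param label_set Optional label universe; labels without time get 0.
#' @return Named fractions summing to 1.
#' @export
time_shares <- function(timeline, label_set = NULL) {
  dur <- timeline$end - timeline$start
  total <- sum(dur)
  if (total <= 0) stop("timeline has zero duration", call. = FALSE)
  sh <- tapply(dur, timeline$label, sum) / total
  sh <- stats::setNames(as.numeric(sh), names(sh))
  if (!is.null(label_set)) {
    out <- stats::setNames(numeric(length(label_set)), label_set)
    out[names(sh)] <- sh
    sh <- out
  }
  sh
}

#' Cohort summary of per-scan time shares
#'
#' Mean share percentage per label with a Student-t 95% confidence interval
#' over scans.
#'
#' @param shares Matrix or data frame, scans x labels, of per-scan share
#'   fractions (rows summing to 1).
#' @param conf Confidence level (default 0.95).
#' @return Data frame `label`, `mean_pct`, `ci_lo`, `ci_hi`, `n_scans`.
#' @export
cohort_summary <- function(shares, conf = 0.95) {
  shares <- as.matrix(shares)
  n <- nrow(shares)
  if (n < 2) stop("need at least 2 scans for a cohort summary",
                  call. = FALSE)
  m <- colMeans(shares) * 100
  se <- apply(shares, 2, stats::sd) / sqrt(n) * 100
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  data.frame(label = colnames(shares), mean_pct = as.numeric(m),
             ci_lo = as.numeric(m - tcrit * se),
             ci_hi = as.numeric(m + tcrit * se),
             n_scans = n, row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-scan shares matrix for a list of timelines
#'
#' @param timelines List of timeline data frames.
#' @param label_set Label universe for the columns.
#' @return Matrix scans x labels of share fractions.
#' @export
shares_matrix <- function(timelines, label_set = scan_labels()) {
  t(vapply(timelines, time_shares, numeric(length(label_set)),
           label_set = label_set))
}

#' Duration-normalized timeline matrix
#'
#' Resamples each scan to `n_bins` equal time bins; the bin label is the
#' majority label (by time) within the bin — the representation behind
#' "anatomy versus normalized scan time" cohort displays.
#'
#' @param timelines List of timeline data frames.
#' @param n_bins Number of bins (default 100).
#' @return Character matrix, scans x bins.
#' @export
normalized_timeline_matrix <- function(timelines, n_bins = 100) {
  t(vapply(timelines, function(tl) {
    dur <- max(tl$end)
    edges <- seq(0, dur, length.out = n_bins + 1)
    vapply(seq_len(n_bins), function(b) {
      ov <- pmax(0, pmin(tl$end, edges[b + 1]) - pmax(tl$start, edges[b]))
      by_lab <- tapply(ov, tl$label, sum)
      names(by_lab)[which.max(by_lab)]
    }, character(1))
  }, character(n_bins)))
}

#' Confusion matrix and overall agreement between two labelings
#'
#' @param labels_a Reference labels (rows).
#' @param labels_b Comparison labels (columns), same length.
#' @param label_set Optional label universe fixing the matrix dimensions.
#' @return List with `counts` (matrix), `agreement` (matching fraction),
#'   `row_normalized` (rows summing to 1 where the row total is positive),
#'   `n`.
#' @export
confusion <- function(labels_a, labels_b, label_set = NULL) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length", call. = FALSE)
  if (is.null(label_set)) label_set <- sort(unique(c(labels_a, labels_b)))
  fa <- factor(labels_a, levels = label_set)
  fb <- factor(labels_b, levels = label_set)
  counts <- table(reference = fa, comparison = fb)
  counts <- matrix(as.integer(counts), nrow = length(label_set),
                   dimnames = list(reference = label_set,
                                   comparison = label_set))
  rn <- counts / pmax(rowSums(counts), 1)
  list(counts = counts,
       agreement = sum(diag(counts)) / length(labels_a),
       row_normalized = rn,
       n = length(labels_a))
}

#' Pearson correlation between two share vectors
#'
#' Used to compare two labelings of the same cohort through their flattened
#' per-scan-per-label duration shares.
#'
#' @param shares_a,shares_b Numeric vectors (or matrices, flattened) of
#'   equal length.
#' @return Sample Pearson correlation coefficient.
#' @export
share_correlation <- function(shares_a, shares_b) {
  a <- as.numeric(shares_a); b <- as.numeric(shares_b)
  if (length(a) != length(b))
    stop("share vectors must have equal length", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("share vectors have zero variance", call. = FALSE)
  stats::cor(a, b)
}

#' Nearest-centroid baseline clip classifier
#'
#' Desk-scale stand-in for a learned video classifier: predicts the label
#' of each clip feature vector by its nearest centroid (Euclidean);
#' distance ties break to the lexicographically first label.
#'
#' @param features Numeric matrix (clips x dims) or a clips data frame with
#'   `f1..fd` columns from [attach_clip_features()].
#' @param centroids Matrix labels x dims with label row names (see
#'   [label_centroids()]).
#' @return Character vector of predicted labels.
#' @export
baseline_classify <- function(features, centroids) {
  if (is.data.frame(features)) {
    fcols <- grep("^f\\d+$", names(features), value = TRUE)
    features <- as.matrix(features[, fcols, drop = FALSE])
  }
  if (ncol(features) != ncol(centroids))
    stop("feature and centroid dimensions differ", call. = FALSE)
  labs <- rownames(centroids)
  ord <- order(labs) # lexicographic tie-break via column order + which.min
  cent <- centroids[ord, , drop = FALSE]
  labs <- labs[ord]
  d2 <- outer(rowSums(features^2), rep(1, nrow(cent))) -
    2 * features %*% t(cent) +
    outer(rep(1, nrow(features)), rowSums(cent^2))
  labs[apply(d2, 1, which.min)]
}

#' Expected accuracy of the one-hot nearest-centroid channel
#'
#' For unit-separated one-hot centroids with isotropic Gaussian feature
#' noise `sigma`, classification reduces to an argmax over feature
#' components, so the accuracy has the closed form
#' `P(Z_1 + 1/sigma > max of K-1 standard normals)`.
#'
#' @param sigma Feature noise standard deviation.
#' @param k Number of labels.
#' @return Expected accuracy in `(0, 1)`.
#' @export
centroid_channel_accuracy <- function(sigma, k) {
  f <- function(z) stats::dnorm(z) * stats::pnorm(z + 1 / sigma)^(k - 1)
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
}

#' Calibrate feature noise for a target classifier accuracy
#'
#' Inverts [centroid_channel_accuracy()] by root finding.
#'
#' @param accuracy Target accuracy in (1/k, 1).
#' @param k Number of labels.
#' @return Noise standard deviation `sigma`.
#' @export
calibrate_feature_noise <- function(accuracy, k) {
  stopifnot(accuracy > 1 / k, accuracy < 1)
  stats::uniroot(function(s) centroid_channel_accuracy(s, k) - accuracy,
                 interval = c(1e-3, 50), tol = 1e-9)$root
}

#' Corrupt a label vector to a target expected agreement
#'
#' Symmetric label-noise channel: each label is kept with probability
#' `agreement` and otherwise replaced by a uniformly drawn *different*
#' label, so the expected fraction of matches equals `agreement` exactly.
#' Calibrated to a reported human-vs-automatic agreement, this emulates an
#' imperfect automatic labeler for agreement-machinery studies.
#'
#' @param labels Character vector of true labels.
#' @param agreement Target expected agreement in `[0, 1]`.
#' @param label_set Label universe to draw replacements from.
#' @return Corrupted character vector, same length.
#' @export
corrupt_labels <- function(labels, agreement,
                           label_set = scan_labels()) {
  stopifnot(agreement >= 0, agreement <= 1, length(label_set) >= 2)
  out <- labels
  flip <- stats::runif(length(labels)) >= agreement
  for (i in which(flip)) {
    alt <- setdiff(label_set, labels[i])
    out[i] <- alt[sample.int(length(alt), 1)]
  }
  out
}
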