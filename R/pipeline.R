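# Session serialization and the stage-wise analysis pipeline
# (simulate -> extract -> clips -> gaze -> motion -> workflow -> language
# -> report), file-based so stages can be toggled and audited
# independently.  Data goes to files; logs go to stderr.

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a scan session to a directory
#'
#' Emits the standard interchange layout: `gaze.csv`, `imu.csv`,
#' `ui.jsonl` (one state record per frame), `timeline.csv`,
#' `transcript.txt`, `truth.json` (ground-truth events, freezes, gaze
#' bookkeeping), `config.yaml`, and optionally rendered `frames/*.png`.
#' Only streams present in the session are written.
#'
#' @param session A `scan_session`.
#' @param dir Output directory (created).
#' @param frames Also render and write PNG frames (slow; intended for small
#'   sessions).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, frames = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(session$gaze))
    write_csv_plain(session$gaze, file.path(dir, "gaze.csv"))
  if (!is.null(session$imu))
    write_csv_plain(session$imu, file.path(dir, "imu.csv"))
  if (!is.null(session$ui)) {
    con <- file(file.path(dir, "ui.jsonl"), "w")
    jsonlite::stream_out(session$ui, con, verbose = FALSE, digits = NA)
    close(con)
  }
  write_csv_plain(session$timeline, file.path(dir, "timeline.csv"))
  if (!is.null(session$transcript))
    writeLines(vapply(session$transcript, paste, character(1),
                      collapse = " "),
               file.path(dir, "transcript.txt"))
  truth <- list(scan_id = session$scan_id, duration = session$duration,
                seed = session$config$seed, ti = session$ti,
                events = session$events, freezes = session$freezes,
                gaze_truth = session$gaze_truth)
  if (!is.null(session$clip_features))
    truth$clip_features <- session$clip_features
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  cfg <- session$config
  yaml::write_yaml(list(seed = cfg$seed, frame_rate = cfg$frame_rate,
                        gaze_rate = cfg$gaze_rate, imu_rate = cfg$imu_rate,
                        duration_mean = cfg$duration_mean,
                        duration_sd = cfg$duration_sd,
                        duration_bounds = cfg$duration_bounds,
                        time_shares = as.list(cfg$time_shares),
                        pos_weights = as.list(cfg$pos_weights)),
                  file.path(dir, "config.yaml"))
  if (frames && !is.null(session$ui)) {
    ras <- lapply(seq_len(nrow(session$ui)), function(i)
      render_ui_frame(session$ui[i, ]))
    write_ui_frames(ras, file.path(dir, "frames"))
  }
  invisible(dir)
}

#' Read a scan session directory back into memory
#'
#' @param dir Directory written by [write_session()].
#' @return A `scan_session`-like list (without the generator config).
#' @export
read_session <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  s <- list(scan_id = truth$scan_id, duration = truth$duration,
            ti = truth$ti,
            timeline = utils::read.csv(file.path(dir, "timeline.csv"),
                                       stringsAsFactors = FALSE),
            events = as.data.frame(truth$events),
            freezes = as.data.frame(truth$freezes),
            gaze_truth = truth$gaze_truth)
  if (!is.null(truth$clip_features))
    s$clip_features <- as.data.frame(truth$clip_features)
  gp <- file.path(dir, "gaze.csv")
  if (file.exists(gp)) s$gaze <- utils::read.csv(gp)
  ip <- file.path(dir, "imu.csv")
  if (file.exists(ip)) s$imu <- utils::read.csv(ip)
  up <- file.path(dir, "ui.jsonl")
  if (file.exists(up)) {
    con <- file(up, "r")
    s$ui <- jsonlite::stream_in(con, verbose = FALSE)
    close(con)
    if (!"meas_type" %in% names(s$ui)) s$ui$meas_type <- NA_character_
    if (!"meas_value" %in% names(s$ui)) s$ui$meas_value <- NA_real_
  }
  tp <- file.path(dir, "transcript.txt")
  if (file.exists(tp)) {
    s$transcript <- lapply(readLines(tp), function(l)
      strsplit(l, " ", fixed = TRUE)[[1]])
  }
  class(s) <- "scan_session"
  s
}

#' Pipeline run configuration
#'
#' @param out_dir Output directory of the run.
#' @param generator A [generator_config()].
#' @param n_scans Number of scans to simulate.
#' @param stages Stages to execute, in order, from
#'   `c("simulate", "extract", "clips", "gaze", "motion", "workflow",
#'   "language", "report")`.
#' @param duration_min Optional fixed scan duration, minutes.
#' @param clip_len Clip length, seconds.
#' @param min_fix,merge_gap Fixation detector thresholds, seconds.
#' @param meas_window Biometry gaze audit half-window, seconds.
#' @param target_agreement Expected accuracy to which the baseline clip
#'   classifier's feature noise is calibrated in the workflow stage
#'   (`NULL` keeps the generator's `feature_noise_sd`).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(out_dir,
                       generator = generator_config(),
                       n_scans = 2,
                       stages = c("simulate", "extract", "clips", "gaze",
                                  "motion", "workflow", "language",
                                  "report"),
                       duration_min = NULL,
                       clip_len = 5, min_fix = 0.1, merge_gap = 0.4,
                       meas_window = 2, target_agreement = NULL) {
  rc <- list(out_dir = out_dir, generator = generator, n_scans = n_scans,
             stages = stages, duration_min = duration_min,
             clip_len = clip_len, min_fix = min_fix,
             merge_gap = merge_gap, meas_window = meas_window,
             target_agreement = target_agreement)
  class(rc) <- "run_config"
  rc
}

stage_input <- function(path, stage) {
  if (!file.exists(path))
    stop(sprintf("pipeline stage '%s': missing input %s", stage,
                 basename(path)), call. = FALSE)
  path
}

session_dirs <- function(out_dir) {
  sort(list.dirs(file.path(out_dir, "sessions"), recursive = FALSE))
}

#' Run the scan-analysis pipeline
#'
#' Executes the enabled stages in order against `out_dir`; each stage reads
#' only files written by earlier stages and fails fast, naming itself, when
#' an input is missing.  The final report aggregates cohort time shares,
#' clip prevalence, gaze audits, classifier agreement, and language
#' statistics.  Reruns with the same configuration are byte-identical.
#'
#' @param rc A [run_config()].
#' @return The report list, invisibly; `report.json` and per-stage outputs
#'   are written under `rc$out_dir`.
#' @export
run_pipeline <- function(rc) {
  out <- rc$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  fr <- rc$generator$frame_rate
  t_run0 <- proc.time()[["elapsed"]]
  log <- function(stage, t0)
    message(sprintf("[%s] done in %.2f s", stage,
                    proc.time()[["elapsed"]] - t0))

  if ("simulate" %in% rc$stages) {
    t0 <- proc.time()[["elapsed"]]
    streams <- c("ui", "gaze", "transcript", "clips")
    if ("motion" %in% rc$stages) streams <- c(streams, "imu")
    sessions <- simulate_cohort(rc$generator, rc$n_scans,
                                streams = streams,
                                duration_min = rc$duration_min)
    for (s in sessions)
      write_session(s, file.path(out, "sessions", s$scan_id))
    log("simulate", t0)
  }

  dirs <- session_dirs(out)

  if ("extract" %in% rc$stages) {
    t0 <- proc.time()[["elapsed"]]
    if (length(dirs) == 0)
      stop("pipeline stage 'extract': no session directories found",
           call. = FALSE)
    for (d in dirs) {
      con <- file(stage_input(file.path(d, "ui.jsonl"), "extract"), "r")
      ui <- jsonlite::stream_in(con, verbose = FALSE)
      close(con)
      if (!"meas_type" %in% names(ui)) ui$meas_type <- NA_character_
      if (!"meas_value" %in% names(ui)) ui$meas_value <- NA_real_
      ev <- extract_event_timeline(ui, frame_rate = fr)
      con <- file(file.path(d, "events.jsonl"), "w")
      jsonlite::stream_out(ev, con, verbose = FALSE, digits = NA)
      close(con)
    }
    log("extract", t0)
  }

  if ("clips" %in% rc$stages) {
    t0 <- proc.time()[["elapsed"]]
    all_clips <- list()
    for (d in dirs) {
      con <- file(stage_input(file.path(d, "events.jsonl"), "clips"), "r")
      ev <- jsonlite::stream_in(con, verbose = FALSE)
      close(con)
      s <- read_session(d)
      cl <- extract_clips(ev, s$duration, clip_len = rc$clip_len,
                          scan_id = s$scan_id)
      cl <- assign_truth_label(cl, s$timeline)
      if (!is.null(s$clip_features))
        cl <- attach_clip_features(cl, s)
      all_clips[[d]] <- cl
    }
    write_csv_plain(do.call(rbind, all_clips),
                    file.path(out, "clips.csv"))
    log("clips", t0)
  }

  if ("gaze" %in% rc$stages) {
    t0 <- proc.time()[["elapsed"]]
    eps <- list(); flags <- logical(0); sess <- list()
    for (d in dirs) {
      stage_input(file.path(d, "gaze.csv"), "gaze")
      s <- read_session(d)
      sess[[d]] <- s
      for (nm in default_aois()$name) {
        e <- detect_fixation_episodes(s$gaze, nm, rc$min_fix,
                                      rc$merge_gap)
        if (nrow(e) > 0) eps[[paste(d, nm)]] <- cbind(
          data.frame(scan_id = s$scan_id), e)
      }
      flags <- c(flags, scan_aoi_flag(s$gaze, "bioeffect_box",
                                      rc$min_fix, rc$merge_gap))
    }
    episodes <- if (length(eps)) do.call(rbind, eps) else
      data.frame(scan_id = character(), aoi = character(),
                 t_start = numeric(), t_end = numeric(),
                 n_fixations = integer())
    rownames(episodes) <- NULL
    write_csv_plain(episodes, file.path(out, "episodes.csv"))
    n_meas <- sum(vapply(sess, function(s)
      sum(s$events$kind == "measurement_display"), numeric(1)))
    audit <- list(
      n_scans = length(dirs),
      bioeffect_looked_rate = mean(flags),
      measurement_gaze = if (n_meas > 0)
        measurement_gaze_rate(unname(sess), window = rc$meas_window,
                              min_fix = rc$min_fix,
                              merge_gap = rc$merge_gap) else NULL)
    jsonlite::write_json(audit, file.path(out, "audit_report.json"),
                         auto_unbox = TRUE, digits = NA)
    log("gaze", t0)
  }

  if ("motion" %in% rc$stages) {
    t0 <- proc.time()[["elapsed"]]
    for (d in dirs) {
      imu <- utils::read.csv(stage_input(file.path(d, "imu.csv"),
                                         "motion"))
      traj <- fuse_stream(imu)
      write_csv_plain(traj, file.path(d, "orientation.csv"))
    }
    log("motion", t0)
  }

  if ("workflow" %in% rc$stages) {
    t0 <- proc.time()[["elapsed"]]
    timelines <- lapply(dirs, function(d)
      utils::read.csv(stage_input(file.path(d, "timeline.csv"),
                                  "workflow"), stringsAsFactors = FALSE))
    sh <- shares_matrix(timelines, rc$generator$label_set)
    write_csv_plain(data.frame(scan_id = basename(dirs), sh),
                    file.path(out, "shares.csv"))
    if (length(dirs) >= 2)
      write_csv_plain(cohort_summary(sh),
                      file.path(out, "cohort_summary.csv"))
    clips <- utils::read.csv(stage_input(file.path(out, "clips.csv"),
                                         "workflow"),
                             stringsAsFactors = FALSE)
    cen <- label_centroids(rc$generator$label_set,
                           rc$generator$feature_dim)
    fcols <- grep("^f\\d+$", names(clips), value = TRUE)
    conf <- NULL
    if (length(fcols) > 0 && nrow(clips) > 0) {
      pred <- baseline_classify(as.matrix(clips[, fcols]), cen)
      conf <- confusion(clips$label, pred, rc$generator$label_set)
      write_csv_plain(as.data.frame(conf$counts),
                      file.path(out, "confusion.csv"))
    }
    ntm <- normalized_timeline_matrix(timelines)
    write_csv_plain(as.data.frame(ntm),
                    file.path(out, "timelines_matrix.csv"))
    jsonlite::write_json(
      list(prevalence = as.list(clip_prevalence(clips)),
           agreement = if (!is.null(conf)) conf$agreement else NULL),
      file.path(out, "workflow_stats.json"), auto_unbox = TRUE,
      digits = NA)
    log("workflow", t0)
  }

  if ("language" %in% rc$stages) {
    t0 <- proc.time()[["elapsed"]]
    corpus <- list()
    for (d in dirs) {
      p <- stage_input(file.path(d, "transcript.txt"), "language")
      corpus <- c(corpus, lapply(readLines(p), function(l)
        strsplit(l, " ", fixed = TRUE)[[1]]))
    }
    st <- corpus_stats(corpus, rc$generator$lexicon)
    jsonlite::write_json(st, file.path(out, "language_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    log("language", t0)
  }

  report <- list(seed = rc$generator$seed, n_scans = length(dirs),
                 stages = rc$stages)
  if ("report" %in% rc$stages) {
    t0 <- proc.time()[["elapsed"]]
    grab <- function(p) if (file.exists(p))
      jsonlite::read_json(p, simplifyVector = TRUE) else NULL
    cs <- file.path(out, "cohort_summary.csv")
    report$cohort_summary <- if (file.exists(cs))
      utils::read.csv(cs, stringsAsFactors = FALSE) else NULL
    report$workflow <- grab(file.path(out, "workflow_stats.json"))
    report$gaze_audit <- grab(file.path(out, "audit_report.json"))
    report$language <- grab(file.path(out, "language_stats.json"))
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    log("report", t0)
  }
  message(sprintf("pipeline finished in %.2f s",
                  proc.time()[["elapsed"]] - t_run0))
  invisible(report)
}
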