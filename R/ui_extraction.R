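# Recovery of machine events (freeze, saves, displayed measurement values)
# from the per-frame UI stream, either from structured records or from
# rendered screen rasters via template-matching character recognition.

#' Read a numeric value from a raster region by glyph template matching
#'
#' The region is split into fixed-pitch character cells; each cell is scored
#' against every glyph by the fraction of agreeing pixels and must match its
#' best glyph at least at `threshold` (default 0.99, i.e. exactly for 3x5
#' glyphs).  Trailing blank cells terminate the string.  Any corrupted or
#' ambiguous cell makes the result unreadable: no value is ever fabricated.
#'
#' @param raster 0/1 matrix (one rendered frame).
#' @param region Single-row data frame with `row0`, `col0`, `row1`, `col1`
#'   (1-based inclusive), e.g. one row of [ui_regions()].
#' @param glyphs Template set, see [ui_glyphs()].
#' @param threshold Minimum per-character match score in `[0, 1]`.
#' @return List with `value` (numeric or `NA`), `confidence` (worst
#'   per-character score, 0 for blank regions), `readable` (logical).
#' @export
read_numeric_box <- function(raster, region, glyphs = ui_glyphs(),
                             threshold = 0.99) {
  if (region$row1 < region$row0 || region$col1 < region$col0)
    stop("empty region", call. = FALSE)
  if (region$row1 > nrow(raster) || region$col1 > ncol(raster))
    stop("region outside raster bounds", call. = FALSE)
  sub <- raster[region$row0:region$row1, region$col0:region$col1,
                drop = FALSE]
  unreadable <- list(value = NA_real_, confidence = 0, readable = FALSE)
  n_cells <- (ncol(sub) - 1) %/% GLYPH_PITCH
  if (n_cells < 1 || nrow(sub) < GLYPH_H + 1) return(unreadable)

  chars <- character(0)
  scores <- numeric(0)
  for (k in seq_len(n_cells)) {
    c0 <- 2 + (k - 1) * GLYPH_PITCH
    cell <- sub[2:(1 + GLYPH_H), c0:(c0 + GLYPH_W - 1)]
    if (all(cell == 0)) { chars <- c(chars, ""); scores <- c(scores, 1); next }
    sc <- vapply(glyphs, function(g) mean(cell == g), numeric(1))
    best <- which.max(sc)
    chars <- c(chars, names(glyphs)[best])
    scores <- c(scores, sc[best])
  }
  nonblank <- which(chars != "")
  if (length(nonblank) == 0) return(unreadable)
  span <- seq(min(nonblank), max(nonblank))
  if (any(chars[span] == "")) return(unreadable) # internal gap: corrupted
  if (any(scores[span] < threshold)) return(unreadable)
  text <- paste(chars[span], collapse = "")
  value <- suppressWarnings(as.numeric(text))
  if (is.na(value)) return(unreadable)
  list(value = value, confidence = min(scores[span]), readable = TRUE)
}

read_icon_box <- function(raster, region) {
  sub <- raster[region$row0:region$row1, region$col0:region$col1,
                drop = FALSE]
  if (all(sub == save_icon("image_save"))) return("image_save")
  if (all(sub == save_icon("clip_save"))) return("clip_save")
  if (all(sub == 0)) return("none")
  "unreadable"
}

#' Decode one rendered UI raster back to a structured state record
#'
#' Inverse of [render_ui_frame()] for noise-free rasters: reads the freeze
#' and save indicator boxes and all numeric boxes.
#'
#' @inheritParams read_numeric_box
#' @return One-row data frame with `frozen`, `save`, `meas_type`,
#'   `meas_value`, `ti`, `readable`.
#' @export
decode_ui_raster <- function(raster, glyphs = ui_glyphs(),
                             threshold = 0.99) {
  reg <- ui_regions()
  rg <- function(nm) reg[reg$name == nm, , drop = FALSE]
  fr <- rg("freeze_box")
  fsub <- raster[fr$row0:fr$row1, fr$col0:fr$col1]
  frozen <- if (all(fsub == 1)) TRUE else if (all(fsub == 0)) FALSE else NA
  save <- read_icon_box(raster, rg("save_box"))
  vals <- lapply(c(HC = "hc_box", AC = "ac_box", FL = "fl_box"),
                 function(nm) read_numeric_box(raster, rg(nm), glyphs,
                                               threshold))
  shown <- names(vals)[vapply(vals, function(v) v$readable, logical(1))]
  ti <- read_numeric_box(raster, rg("ti_box"), glyphs, threshold)
  readable <- !is.na(frozen) && save != "unreadable" && length(shown) <= 1
  data.frame(
    frozen = isTRUE(frozen),
    save = if (save == "unreadable") "none" else save,
    meas_type = if (length(shown) == 1) shown else NA_character_,
    meas_value = if (length(shown) == 1) vals[[shown]]$value else NA_real_,
    ti = if (ti$readable) ti$value else NA_real_,
    readable = readable,
    stringsAsFactors = FALSE)
}

new_events <- function() {
  data.frame(kind = character(), t = numeric(), frame = integer(),
             meas_type = character(), meas_value = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect freeze on/off transitions in a UI stream
#'
#' Emits one `freeze_on` event per false-to-true transition of the frozen
#' flag and one `freeze_off` per true-to-false transition; timestamps are
#' `frame / frame_rate` (0-based frames).  Events strictly alternate by
#' construction.
#'
#' @param ui Data frame with columns `frame` (0-based, in order) and
#'   `frozen` (logical).
#' @param frame_rate Frames per second.
#' @return Events data frame (`kind`, `t`, `frame`, `meas_type`,
#'   `meas_value`).
#' @export
detect_freeze_transitions <- function(ui, frame_rate = 30) {
  if (nrow(ui) == 0) return(new_events())
  fz <- as.logical(ui$frozen)
  ch <- which(diff(fz) != 0) + 1L
  if (length(ch) == 0) return(new_events())
  data.frame(kind = ifelse(fz[ch], "freeze_on", "freeze_off"),
             t = ui$frame[ch] / frame_rate,
             frame = as.integer(ui$frame[ch]),
             meas_type = NA_character_, meas_value = NA_real_,
             stringsAsFactors = FALSE)
}

#' Extract the full machine event timeline from a UI stream
#'
#' Union of freeze transitions, image/clip save events, and
#' `measurement_display` events, sorted by time.  A measurement event is
#' emitted when a measurement box becomes readable with a new value (value
#' change, not per frame); repeats of the same value within the `debounce`
#' window are suppressed.  Input may be a structured per-frame data frame
#' (columns `frame`, `frozen`, `save`, `meas_type`, `meas_value`), a list of
#' rendered rasters, or a directory of `frame_*.png` files; rasters are
#' decoded with [decode_ui_raster()] and unreadable frames are logged and
#' skipped, never guessed.
#'
#' @param ui Structured UI data frame, list of rasters, or frames directory.
#' @param frame_rate Frames per second.
#' @param debounce Suppression window for repeated identical measurement
#'   values, seconds.
#' @param glyphs Glyph set for raster decoding.
#' @return Events data frame sorted by `t` (columns `kind`, `t`, `frame`,
#'   `meas_type`, `meas_value`).
#' @export
extract_event_timeline <- function(ui, frame_rate = 30, debounce = 0.5,
                                   glyphs = ui_glyphs()) {
  if (is.character(ui) && length(ui) == 1) ui <- read_ui_frames(ui)
  if (is.list(ui) && !is.data.frame(ui)) {
    rows <- lapply(seq_along(ui), function(i) {
      d <- decode_ui_raster(ui[[i]], glyphs)
      if (!d$readable) {
        message(sprintf("frame %d: unreadable UI raster, skipped", i - 1L))
        return(NULL)
      }
      d$frame <- i - 1L
      d
    })
    ui <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(ui)) return(new_events())
  }
  ev <- detect_freeze_transitions(ui, frame_rate)

  sv <- which(!is.na(ui$save) & ui$save != "none")
  if (length(sv) > 0)
    ev <- rbind(ev, data.frame(kind = ui$save[sv],
                               t = ui$frame[sv] / frame_rate,
                               frame = as.integer(ui$frame[sv]),
                               meas_type = NA_character_,
                               meas_value = NA_real_,
                               stringsAsFactors = FALSE))

  shown <- !is.na(ui$meas_value) & !is.na(ui$meas_type)
  prev_val <- c(NA_real_, ui$meas_value[-nrow(ui)])
  prev_type <- c(NA_character_, ui$meas_type[-nrow(ui)])
  cand <- which(shown & (is.na(prev_val) | ui$meas_value != prev_val |
                           ui$meas_type != prev_type))
  if (length(cand) > 0) {
    keep <- logical(length(cand))
    last_t <- c(HC = -Inf, AC = -Inf, FL = -Inf)
    last_v <- c(HC = NA_real_, AC = NA_real_, FL = NA_real_)
    for (i in seq_along(cand)) {
      r <- cand[i]
      ty <- ui$meas_type[r]
      t <- ui$frame[r] / frame_rate
      dup <- !is.na(last_v[ty]) && ui$meas_value[r] == last_v[ty] &&
        (t - last_t[ty]) <= debounce
      if (!dup) {
        keep[i] <- TRUE
        last_t[ty] <- t
        last_v[ty] <- ui$meas_value[r]
      }
    }
    cand <- cand[keep]
    if (length(cand) > 0)
      ev <- rbind(ev, data.frame(kind = "measurement_display",
                                 t = ui$frame[cand] / frame_rate,
                                 frame = as.integer(ui$frame[cand]),
                                 meas_type = ui$meas_type[cand],
                                 meas_value = ui$meas_value[cand],
                                 stringsAsFactors = FALSE))
  }
  ev[order(ev$t, ev$frame, ev$kind), , drop = FALSE]
}

#' Count displayed biometric measurements by type
#'
#' @param events Events data frame from [extract_event_timeline()].
#' @return Named list with `HC`, `AC`, `FL` counts and their `total`.
#' @export
count_biometric_measurements <- function(events) {
  me <- events[events$kind == "measurement_display", , drop = FALSE]
  out <- list(HC = sum(me$meas_type == "HC", na.rm = TRUE),
              AC = sum(me$meas_type == "AC", na.rm = TRUE),
              FL = sum(me$meas_type == "FL", na.rm = TRUE))
  out$total <- out$HC + out$AC + out$FL
  out
}
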