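# Deterministic rendering of machine UI state into small binary rasters.
# The renderer draws its own fixed-pitch 3x5 glyphs at documented
# rectangles, so the downstream template-matching reader can recover every
# displayed value exactly; real scanner skins are out of scope.

#' Glyph set for the UI renderer
#'
#' Binary 5-row by 3-column bitmaps for the digits 0-9 and the decimal
#' point, used both to render numeric boxes and as the template set of
#' [read_numeric_box()].
#'
#' @return Named list of 5x3 0/1 matrices.
#' @export
ui_glyphs <- function() {
  g <- function(...) matrix(c(...), nrow = 5, byrow = TRUE)
  list(
    "0" = g(1,1,1, 1,0,1, 1,0,1, 1,0,1, 1,1,1),
    "1" = g(0,1,0, 1,1,0, 0,1,0, 0,1,0, 1,1,1),
    "2" = g(1,1,1, 0,0,1, 1,1,1, 1,0,0, 1,1,1),
    "3" = g(1,1,1, 0,0,1, 0,1,1, 0,0,1, 1,1,1),
    "4" = g(1,0,1, 1,0,1, 1,1,1, 0,0,1, 0,0,1),
    "5" = g(1,1,1, 1,0,0, 1,1,1, 0,0,1, 1,1,1),
    "6" = g(1,1,1, 1,0,0, 1,1,1, 1,0,1, 1,1,1),
    "7" = g(1,1,1, 0,0,1, 0,0,1, 0,1,0, 0,1,0),
    "8" = g(1,1,1, 1,0,1, 1,1,1, 1,0,1, 1,1,1),
    "9" = g(1,1,1, 1,0,1, 1,1,1, 0,0,1, 1,1,1),
    "." = g(0,0,0, 0,0,0, 0,0,0, 0,0,0, 0,1,0))
}

GLYPH_H <- 5L
GLYPH_W <- 3L
GLYPH_PITCH <- 4L # glyph width + 1 blank separator column

#' Named rectangles of the rendered UI canvas
#'
#' Fixed, documented layout of the synthetic machine interface: a freeze
#' indicator and a save indicator (8x8 icon boxes), one numeric box per
#' biometric measurement type (HC, AC, FL) and one for the displayed thermal
#' index.  Coordinates are 1-based inclusive row/column bounds on the
#' `r ui_canvas_size()[1]` x `r ui_canvas_size()[2]` canvas.
#'
#' @return Data frame with columns `name`, `row0`, `col0`, `row1`, `col1`.
#' @export
ui_regions <- function() {
  data.frame(
    name = c("freeze_box", "save_box", "hc_box", "ac_box", "fl_box",
             "ti_box"),
    row0 = c(3, 3, 14, 14, 14, 24),
    col0 = c(3, 14, 3, 33, 63, 3),
    row1 = c(10, 10, 20, 20, 20, 30),
    col1 = c(10, 21, 28, 58, 88, 28),
    stringsAsFactors = FALSE)
}

#' @rdname ui_regions
#' @export
ui_canvas_size <- function() c(rows = 40L, cols = 100L)

save_icon <- function(kind) {
  if (kind == "image_save") matrix(1, 8, 8)
  else if (kind == "clip_save") matrix(rep(c(1, 0), length.out = 8), 8, 8)
  else matrix(0, 8, 8)
}

draw_text <- function(canvas, text, region, glyphs) {
  chars <- strsplit(text, "")[[1]]
  max_chars <- (region$col1 - region$col0) %/% GLYPH_PITCH
  if (length(chars) > max_chars)
    stop(sprintf("render error: '%s' does not fit in region %s",
                 text, region$name), call. = FALSE)
  if (!all(chars %in% names(glyphs)))
    stop(sprintf("render error: characters of '%s' not in glyph set", text),
         call. = FALSE)
  r0 <- region$row0 + 1
  for (k in seq_along(chars)) {
    c0 <- region$col0 + 1 + (k - 1) * GLYPH_PITCH
    canvas[r0:(r0 + GLYPH_H - 1), c0:(c0 + GLYPH_W - 1)] <-
      glyphs[[chars[k]]]
  }
  canvas
}

format_ui_value <- function(value) formatC(value, format = "f", digits = 1)

#' Render one frame of machine UI state to a binary raster
#'
#' Pure function of the state: the freeze indicator box is filled while
#' frozen, the save box shows a solid (image save) or striped (clip save)
#' icon on the event frame, the active measurement value is drawn into the
#' box of its type, and the thermal index into its own box.  Values are
#' rendered with one decimal digit.
#'
#' @param state List or one-row data frame with fields `frozen` (logical),
#'   `save` (`"none"`, `"image_save"`, `"clip_save"`), `meas_type`
#'   (`NA`, `"HC"`, `"AC"`, `"FL"`), `meas_value` (mm, `NA` when absent),
#'   `ti` (thermal index, `NA` to leave blank).
#' @param glyphs Glyph set, see [ui_glyphs()].
#' @return 0/1 matrix of size [ui_canvas_size()].
#' @export
render_ui_frame <- function(state, glyphs = ui_glyphs()) {
  sz <- ui_canvas_size()
  canvas <- matrix(0, sz[1], sz[2])
  reg <- ui_regions()
  rg <- function(nm) reg[reg$name == nm, , drop = FALSE]
  if (isTRUE(state$frozen)) {
    r <- rg("freeze_box")
    canvas[r$row0:r$row1, r$col0:r$col1] <- 1
  }
  sv <- if (is.null(state$save) || is.na(state$save)) "none" else state$save
  if (sv != "none") {
    r <- rg("save_box")
    canvas[r$row0:r$row1, r$col0:r$col1] <- save_icon(sv)
  }
  if (!is.null(state$meas_type) && !is.na(state$meas_type) &&
      !is.na(state$meas_value)) {
    box <- switch(state$meas_type, HC = "hc_box", AC = "ac_box",
                  FL = "fl_box",
                  stop(sprintf("render error: unknown measurement type '%s'",
                               state$meas_type), call. = FALSE))
    if (state$meas_value <= 0)
      stop("render error: measurement values must be positive",
           call. = FALSE)
    canvas <- draw_text(canvas, format_ui_value(state$meas_value),
                        rg(box), glyphs)
  }
  if (!is.null(state$ti) && !is.na(state$ti))
    canvas <- draw_text(canvas, format_ui_value(state$ti), rg("ti_box"),
                        glyphs)
  canvas
}

#' Write / read UI frame rasters as PNG files
#'
#' Frames are stored as 8-bit grayscale PNGs named `frame_%06d.png`.
#'
#' @param frames List of 0/1 matrices from [render_ui_frame()].
#' @param dir Output directory (created if needed).
#' @return `write_ui_frames`: the directory, invisibly.
#'   `read_ui_frames`: list of 0/1 matrices in frame order.
#' @export
write_ui_frames <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames))
    png::writePNG(frames[[i]], file.path(dir, sprintf("frame_%06d.png",
                                                      i - 1L)))
  invisible(dir)
}

#' @rdname write_ui_frames
#' @export
read_ui_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    round(m)
  })
}
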