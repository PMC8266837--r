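# Screen areas of interest (AOIs). Pixel coordinates, origin top-left,
# half-open rectangles [x0, x1) x [y0, y1) on a 1920 x 1080 display.

#' Default screen areas of interest
#'
#' Named rectangles used to attribute gaze samples on the ultrasound display:
#' the live image area, the thermal-safety ("bioeffect") box near the top
#' right, and the measurement box near the bottom right where biometric
#' results are displayed.
#'
#' @param screen Screen size `c(width, height)` in pixels.
#' @return Data frame with columns `name`, `x0`, `y0`, `x1`, `y1`
#'   (half-open pixel bounds, origin top-left).
#' @export
default_aois <- function(screen = c(1920, 1080)) {
  a <- data.frame(
    name = c("image_area", "bioeffect_box", "measurement_box"),
    x0 = c(260, 1700, 1700),
    y0 = c(60, 40, 850),
    x1 = c(1660, 1880, 1900),
    y1 = c(1000, 120, 1000),
    stringsAsFactors = FALSE)
  stopifnot(all(a$x1 <= screen[1]), all(a$y1 <= screen[2]))
  a
}

aoi_rect <- function(aois, name) {
  r <- aois[aois$name == name, , drop = FALSE]
  if (nrow(r) != 1)
    stop(sprintf("unknown AOI '%s'", name), call. = FALSE)
  r
}

# Vectorized point-in-AOI test; invalid samples are never inside.
in_aoi <- function(x, y, valid, rect) {
  inside <- !is.na(x) & !is.na(y) &
    x >= rect$x0 & x < rect$x1 & y >= rect$y0 & y < rect$y1
  inside & valid
}

#' Read named AOI rectangles from a YAML file
#'
#' Expects a top-level mapping of AOI name to a list with `x0`, `y0`, `x1`,
#' `y1` in pixels.
#'
#' @param path YAML file path.
#' @return Data frame in the [default_aois()] layout.
#' @export
read_aois <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(names(raw), function(nm) {
    r <- raw[[nm]]
    data.frame(name = nm, x0 = r$x0, y0 = r$y0, x1 = r$x1, y1 = r$y1,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Write AOI rectangles to YAML
#' @param aois Data frame in the [default_aois()] layout.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_aois <- function(aois, path) {
  lst <- lapply(seq_len(nrow(aois)), function(i)
    list(x0 = aois$x0[i], y0 = aois$y0[i], x1 = aois$x1[i], y1 = aois$y1[i]))
  names(lst) <- aois$name
  yaml::write_yaml(lst, path)
  invisible(path)
}
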