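#' Screen geometry
#'
#' Physical description of the presentation screen, used to convert between
#' pixel coordinates (top-left origin, y downward) and visual-field degrees
#' (screen-centered, x right-positive, y up-positive). Conversion uses true
#' tangent geometry per axis rather than a single deg/px scale factor, so it
#' is exact off-axis for wide screens.
#'
#' @param width_px,height_px screen resolution in pixels.
#' @param width_cm,height_cm physical screen size in cm.
#' @param distance_cm viewing distance in cm.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry(1920, 1080, 50, 35, 60)
#' px_to_deg(960, 540, geom)  # screen center -> (0, 0)
#' @export
screen_geometry <- function(width_px, height_px, width_cm, height_cm, distance_cm) {
  vals <- c(width_px = width_px, height_px = height_px,
            width_cm = width_cm, height_cm = height_cm,
            distance_cm = distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all screen geometry values must be finite and strictly positive")
  structure(as.list(vals), class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  ext <- screen_extent_deg(x)
  cat(sprintf("screen_geometry: %d x %d px, %.1f x %.1f cm at %.1f cm (%.1f x %.1f deg)\n",
              x$width_px, x$height_px, x$width_cm, x$height_cm, x$distance_cm,
              2 * ext[1], 2 * ext[2]))
  invisible(x)
}

#' Angular half-extent of the screen
#'
#' @param geom a [screen_geometry()].
#' @return Numeric half-angles `c(x, y)` in degrees.
#' @export
screen_extent_deg <- function(geom) {
  c(atan2(geom$width_cm / 2, geom$distance_cm),
    atan2(geom$height_cm / 2, geom$distance_cm)) * 180 / pi
}

#' Convert pixel coordinates to visual-field degrees
#'
#' Input pixels use the tracker convention: origin at the top-left corner,
#' y increasing downward. Output degrees are screen-centered with x
#' right-positive and y up-positive.
#'
#' @param x_px,y_px pixel coordinates (vectors).
#' @param geom a [screen_geometry()].
#' @return data.frame with columns `x`, `y` in degrees.
#' @export
px_to_deg <- function(x_px, y_px, geom) {
  cmx <- geom$width_cm / geom$width_px
  cmy <- geom$height_cm / geom$height_px
  data.frame(
    x = atan2((x_px - geom$width_px / 2) * cmx, geom$distance_cm) * 180 / pi,
    y = atan2((geom$height_px / 2 - y_px) * cmy, geom$distance_cm) * 180 / pi
  )
}

#' Convert visual-field degrees back to pixel coordinates
#'
#' Exact inverse of [px_to_deg()].
#'
#' @param x_deg,y_deg degrees, screen-centered (x right, y up).
#' @param geom a [screen_geometry()].
#' @return data.frame with columns `x`, `y` in pixels (top-left origin).
#' @export
deg_to_px <- function(x_deg, y_deg, geom) {
  cmx <- geom$width_cm / geom$width_px
  cmy <- geom$height_cm / geom$height_px
  data.frame(
    x = geom$distance_cm * tan(x_deg * pi / 180) / cmx + geom$width_px / 2,
    y = geom$height_px / 2 - geom$distance_cm * tan(y_deg * pi / 180) / cmy
  )
}
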