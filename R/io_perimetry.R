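#' Humphrey Field Analyzer test-location layouts
#'
#' Enumerates the standard HFA test-point lattices in right-eye orientation
#' (degrees; x temporal-positive, y up-positive). Both grids live on the
#' 6-degree lattice offset 3 degrees from the meridians:
#' \itemize{
#'   \item 24-2: the 52 lattice points with \eqn{|x|, |y| \le 21} and
#'     \eqn{|x| + |y| \le 30}, plus the two nasal points at (-27, ±3) — 54
#'     locations.
#'   \item 30-2: the 76 lattice points with \eqn{|x|, |y| \le 27} and
#'     \eqn{|x| + |y| \le 36}.
#' }
#' The two blind-spot locations at (15, ±3) are flagged.
#'
#' @param layout `"hfa24_2"` or `"hfa30_2"`.
#' @return data.frame with `location_id`, `x_deg`, `y_deg`, `blind_spot`.
#' @export
hfa_locations <- function(layout = c("hfa24_2", "hfa30_2")) {
  layout <- match.arg(layout)
  if (layout == "hfa24_2") {
    g <- expand.grid(x = seq(-21, 21, by = 6), y = seq(-21, 21, by = 6))
    g <- g[abs(g$x) + abs(g$y) <= 30, ]
    g <- rbind(g, data.frame(x = c(-27, -27), y = c(-3, 3)))
  } else {
    g <- expand.grid(x = seq(-27, 27, by = 6), y = seq(-27, 27, by = 6))
    g <- g[abs(g$x) + abs(g$y) <= 36, ]
  }
  g <- g[order(-g$y, g$x), ]
  data.frame(location_id = seq_len(nrow(g)), x_deg = g$x, y_deg = g$y,
             blind_spot = g$x == 15 & abs(g$y) == 3)
}

#' Perimetry sensitivity field
#'
#' A static automated perimetry (SAP) grid: one dB sensitivity threshold per
#' HFA test location, in right-eye orientation, plus an optional mean
#' deviation (MD).
#'
#' @param sensitivity numeric dB values, one per layout location (ordered as
#'   [hfa_locations()]).
#' @param layout `"hfa24_2"` or `"hfa30_2"`.
#' @param md mean deviation in dB, or NA.
#' @param eye `"left"`, `"right"` or `"integrated"`. Fields are always stored
#'   in right-eye orientation; see `mirror` in [read_sensitivity_grid()].
#' @return An object of class `sensitivity_field` (a data.frame of locations
#'   with attributes `layout`, `md`, `eye`).
#' @export
sensitivity_field <- function(sensitivity, layout = c("hfa24_2", "hfa30_2"),
                              md = NA_real_, eye = c("right", "left", "integrated")) {
  layout <- match.arg(layout)
  eye <- match.arg(eye)
  loc <- hfa_locations(layout)
  if (length(sensitivity) != nrow(loc))
    stop("format error: layout ", layout, " expects ", nrow(loc),
         " sensitivity values, got ", length(sensitivity))
  if (any(sensitivity < 0, na.rm = TRUE))
    stop("sensitivities must be >= 0 dB")
  loc$sensitivity_db <- as.numeric(sensitivity)
  structure(loc, class = c("sensitivity_field", "data.frame"),
            layout = layout, md = md, eye = eye)
}

#' @export
print.sensitivity_field <- function(x, ...) {
  cat(sprintf("sensitivity_field: %s, %s eye, %d locations (%d scored), MD = %s dB\n",
              attr(x, "layout"), attr(x, "eye"), nrow(x), sum(!x$blind_spot),
              format(attr(x, "md"))))
  invisible(x)
}

#' Read a SAP sensitivity grid
#'
#' Expects a CSV with one header row and columns `location_id, x_deg, y_deg,
#' sensitivity_db` (extra columns ignored; an optional `md` column supplies
#' the mean deviation). Values are matched to the canonical layout locations
#' by coordinates. Left-eye fields are mirrored into right-eye orientation
#' when `mirror = TRUE`, which makes the best-location binocular merge a
#' positionwise maximum.
#'
#' @param path CSV file.
#' @param layout `"hfa24_2"` or `"hfa30_2"`.
#' @param eye which eye the file describes.
#' @param mirror mirror a left-eye file into right-eye orientation
#'   (negate x). Default: TRUE when `eye == "left"`.
#' @param md mean deviation override (dB).
#' @return A [sensitivity_field()].
#' @export
read_sensitivity_grid <- function(path, layout = c("hfa24_2", "hfa30_2"),
                                  eye = c("right", "left", "integrated"),
                                  mirror = NULL, md = NA_real_) {
  layout <- match.arg(layout)
  eye <- match.arg(eye)
  if (is.null(mirror)) mirror <- eye == "left"
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("location_id", "x_deg", "y_deg", "sensitivity_db")
  if (!all(need %in% names(df)))
    stop("format error in ", path, ": need columns ", paste(need, collapse = ", "))
  loc <- hfa_locations(layout)
  if (nrow(df) != nrow(loc))
    stop("format error: layout ", layout, " expects ", nrow(loc),
         " locations, file has ", nrow(df))
  if (mirror) df$x_deg <- -df$x_deg
  key <- paste(loc$x_deg, loc$y_deg)
  fkey <- paste(df$x_deg, df$y_deg)
  idx <- match(key, fkey)
  if (anyNA(idx))
    stop("format error: file locations do not match the ", layout, " layout",
         if (mirror) " after mirroring" else "")
  if (is.na(md) && "md" %in% names(df)) md <- df$md[1]
  sensitivity_field(df$sensitivity_db[idx], layout, md = md, eye = eye)
}

#' Write a sensitivity field as SAP CSV
#'
#' @param field a [sensitivity_field()].
#' @param path output CSV.
#' @export
write_sensitivity_grid <- function(field, path) {
  df <- data.frame(location_id = field$location_id, x_deg = field$x_deg,
                   y_deg = field$y_deg, sensitivity_db = field$sensitivity_db,
                   md = attr(field, "md"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
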