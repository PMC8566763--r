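#' Visual-field map grid specification
#'
#' A rectangular grid over gaze-relative (visual-field) coordinates. Bins are
#' half-open `[lo, hi)`. The grid covers `[-half_x, half_x)` by
#' `[-half_y, half_y)`; if a half-angle is not a multiple of the bin size the
#' upper edge is extended to complete the last bin.
#'
#' @param half_x,half_y half-angles in degrees.
#' @param bin bin size in degrees (default 2).
#' @param sigma standard deviation in degrees of the per-fixation Gaussian
#'   used by [fixation_heatmap()] (default 1; reflects tracker accuracy and
#'   approximately the foveal extent).
#' @param central_exclusion exclude the four bins around the origin (used by
#'   Crabb-style saccade maps).
#' @return An object of class `map_spec`.
#' @export
map_spec <- function(half_x, half_y, bin = 2, sigma = 1, central_exclusion = FALSE) {
  stopifnot(bin > 0, half_x > 0, half_y > 0, sigma > 0)
  nx <- ceiling(2 * half_x / bin - 1e-9)
  ny <- ceiling(2 * half_y / bin - 1e-9)
  structure(list(half_x = half_x, half_y = half_y, bin = bin, sigma = sigma,
                 central_exclusion = central_exclusion,
                 x_edges = -half_x + bin * (0:nx), y_edges = -half_y + bin * (0:ny),
                 nx = nx, ny = ny, convention = "vf_deg_centered_right_up"),
            class = "map_spec")
}

#' @export
print.map_spec <- function(x, ...) {
  cat(sprintf("map_spec: %d x %d bins of %g deg over [-%g, %g] x [-%g, %g] deg\n",
              x$nx, x$ny, x$bin, x$half_x, max(x$x_edges), x$half_y, max(x$y_edges)))
  invisible(x)
}

bin_centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' Visual-field map
#'
#' A grid of values over visual-field coordinates. `values` is an ny-by-nx
#' matrix; row 1 is the top of the field (largest y), columns run left to
#' right. Masked (undefined) bins are NA with `mask = TRUE`.
#'
#' @param values numeric matrix (ny rows, nx columns).
#' @param spec the [map_spec()].
#' @param kind one of `"density"`, `"proportion"`, `"mean_vp"`, `"rank"`.
#' @param mask logical matrix of undefined bins (default: `is.na(values)`).
#' @param provenance free-form list (participant, clips, notes).
#' @return An object of class `vf_map`.
#' @export
vf_map <- function(values, spec, kind = c("density", "proportion", "mean_vp", "rank"),
                   mask = NULL, provenance = list()) {
  kind <- match.arg(kind)
  if (!all(dim(values) == c(spec$ny, spec$nx)))
    stop("values must be ", spec$ny, " x ", spec$nx, " for this map_spec")
  if (is.null(mask)) mask <- is.na(values)
  values[mask] <- NA_real_
  structure(list(values = values, mask = mask, spec = spec, kind = kind,
                 provenance = provenance), class = "vf_map")
}

#' @export
print.vf_map <- function(x, ...) {
  cat(sprintf("vf_map (%s): %d x %d bins, %d masked; range [%g, %g]\n",
              x$kind, x$spec$ny, x$spec$nx, sum(x$mask),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Write a visual-field map to disk
#'
#' Writes the value matrix as a tab-delimited file (masked bins as `NA`) plus
#' a JSON sidecar `<path>.json` holding the grid specification, kind and
#' provenance. The pair round-trips losslessly through [read_map()].
#'
#' @param map a [vf_map()].
#' @param path output file.
#' @export
write_map <- function(map, path) {
  m <- map$values
  txt <- apply(m, 1, function(r)
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = "\t"))
  writeLines(txt, path)
  meta <- list(kind = map$kind,
               spec = map$spec[c("half_x", "half_y", "bin", "sigma",
                                 "central_exclusion", "convention")],
               provenance = map$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a visual-field map written by [write_map()]
#'
#' @param path the file given to [write_map()].
#' @return A [vf_map()].
#' @export
read_map <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", na.strings = "NA",
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- map_spec(meta$spec$half_x, meta$spec$half_y, meta$spec$bin,
                   meta$spec$sigma, meta$spec$central_exclusion)
  vf_map(m, spec, kind = meta$kind,
         provenance = as.list(meta$provenance))
}
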