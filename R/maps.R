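as_points <- function(p) {
  if (all(c("dx", "dy") %in% names(p))) cbind(p$dx, p$dy)
  else if (all(c("x", "y") %in% names(p))) cbind(p$x, p$y)
  else stop("points need dx/dy or x/y columns")
}

# Per-axis Gaussian bin masses: n_points x n_bins matrix of
# P(bin_lo <= N(mu_i, sigma) < bin_hi).
axis_mass <- function(mu, edges, sigma) {
  lo <- stats::pnorm(outer(edges[-length(edges)], mu, function(e, m) (e - m) / sigma))
  hi <- stats::pnorm(outer(edges[-1], mu, function(e, m) (e - m) / sigma))
  t(hi - lo)  # n x bins
}

grid_from_bins <- function(mx_cols, my_cols) {
  # my rows = y bins ascending; map rows are top-down: reverse y
  m <- t(my_cols) %*% mx_cols
  m[rev(seq_len(nrow(m))), , drop = FALSE]
}

#' Gaussian fixation heat map
#'
#' Each fixation (in visual-field coordinates) contributes a unit-mass
#' isotropic Gaussian of standard deviation `spec$sigma`; the map stores the
#' exact Gaussian mass falling in each bin (per-axis normal CDF differences),
#' so the total map mass equals the number of fixations up to the mass lost
#' outside the grid.
#'
#' @param points data.frame with `dx`, `dy` (or `x`, `y`) in degrees.
#' @param spec a [map_spec()].
#' @param weights optional per-point weights (used for VP weighting).
#' @return A [vf_map()] of kind `"density"`.
#' @export
fixation_heatmap <- function(points, spec, weights = NULL) {
  P <- as_points(points)
  if (!nrow(P)) {
    return(vf_map(matrix(0, spec$ny, spec$nx), spec, "density"))
  }
  mx <- axis_mass(P[, 1], spec$x_edges, spec$sigma)
  my <- axis_mass(P[, 2], spec$y_edges, spec$sigma)
  if (!is.null(weights)) mx <- mx * weights
  vf_map(grid_from_bins(mx, my), spec, "density")
}

#' Average viewing-priority map
#'
#' Ratio of the VP-weighted Gaussian heat map to the unweighted one: each
#' unmasked bin holds the local fixation-mass-weighted mean VP. Bins whose
#' fixation mass is below `eps` are masked (the continuous VP surface is not
#' defined where nobody looked).
#'
#' @param points data.frame with positions (`dx`,`dy` or `x`,`y`).
#' @param vp numeric VP per point (NA records are dropped).
#' @param spec a [map_spec()].
#' @param eps denominator mask threshold in fixation mass (default 1e-3).
#' @return A [vf_map()] of kind `"mean_vp"`.
#' @export
average_vp_map <- function(points, vp, spec, eps = 1e-3) {
  P <- as_points(points)
  ok <- is.finite(vp)
  P <- P[ok, , drop = FALSE]; vp <- vp[ok]
  if (!nrow(P)) return(vf_map(matrix(NA_real_, spec$ny, spec$nx), spec, "mean_vp"))
  mx <- axis_mass(P[, 1], spec$x_edges, spec$sigma)
  my <- axis_mass(P[, 2], spec$y_edges, spec$sigma)
  den <- grid_from_bins(mx, my)
  num <- grid_from_bins(mx * vp, my)
  vals <- num / den
  vals[den < eps] <- NA_real_
  vf_map(vals, spec, "mean_vp")
}

#' Binned fixation-count map
#'
#' Counts points per grid bin (half-open bins) and normalizes: `"max"`
#' divides by the maximum bin (values in \[0, 1\]); `"sum"` by the total
#' included count (proportions summing to 1); `"none"` keeps raw counts.
#' Points outside the grid are dropped.
#'
#' @param points data.frame with positions.
#' @param spec a [map_spec()].
#' @param normalize `"max"`, `"sum"` or `"none"`.
#' @return A [vf_map()] of kind `"proportion"`.
#' @export
count_map <- function(points, spec, normalize = c("max", "sum", "none")) {
  normalize <- match.arg(normalize)
  P <- as_points(points)
  ix <- findInterval(P[, 1], spec$x_edges, left.open = FALSE)
  iy <- findInterval(P[, 2], spec$y_edges, left.open = FALSE)
  # findInterval is [lo, hi): x == edge goes to the upper bin already
  keep <- ix >= 1 & ix <= spec$nx & iy >= 1 & iy <= spec$ny &
    P[, 1] < max(spec$x_edges) & P[, 2] < max(spec$y_edges)
  m <- matrix(0, spec$ny, spec$nx)
  if (any(keep)) {
    tab <- table(factor(iy[keep], levels = 1:spec$ny),
                 factor(ix[keep], levels = 1:spec$nx))
    m <- matrix(as.numeric(tab), spec$ny, spec$nx)
  }
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (normalize == "max" && max(m) > 0) m <- m / max(m)
  if (normalize == "sum" && sum(m) > 0) m <- m / sum(m)
  vf_map(m, spec, "proportion")
}

central_bins <- function(spec) {
  cx <- bin_centers(spec$x_edges)
  cy <- rev(bin_centers(spec$y_edges))
  list(col = which(abs(cx) < spec$bin), row = which(abs(cy) < spec$bin))
}

#' Crabb-style saccade map
#'
#' Proportion of saccade endpoints (in gaze-relative coordinates) per 2x2
#' degree bin over a 12-by-10 degree half-angle grid, excluding the four
#' central bins (endpoints of very short saccades). Excluded and out-of-grid
#' endpoints are dropped; proportions sum to 1 over the included bins. Use
#' [count_map()] with `central_exclusion = FALSE` for the companion
#' fixation-distribution map that keeps the central bins.
#'
#' @param endpoints data.frame with `dx`, `dy` (deg).
#' @param spec a [map_spec()]; default the 12 x 10 deg half-angle grid.
#' @return A [vf_map()] of kind `"proportion"` with the central bins masked.
#' @export
saccade_map <- function(endpoints, spec = map_spec(12, 10, bin = 2,
                                                   central_exclusion = TRUE)) {
  m <- count_map(endpoints, spec, normalize = "none")
  vals <- m$values
  if (spec$central_exclusion) {
    cb <- central_bins(spec)
    vals[cb$row, cb$col] <- NA_real_
  }
  tot <- sum(vals, na.rm = TRUE)
  if (tot > 0) vals <- vals / tot
  vf_map(vals, spec, "proportion")
}

#' z-normalize a map over its unmasked bins
#'
#' @param map a [vf_map()].
#' @return the map with unmasked values standardized to mean 0, SD 1 (SD-0
#'   maps are centered only).
#' @export
z_normalize_map <- function(map) {
  v <- map$values[!map$mask]
  s <- stats::sd(v)
  vals <- map$values - mean(v)
  if (is.finite(s) && s > 0) vals <- vals / s
  vf_map(vals, map$spec, map$kind, mask = map$mask, provenance = map$provenance)
}

#' Relative rank map of a patient against control maps
#'
#' All maps are z-normalized per participant over unmasked bins, then each
#' bin receives the patient's mid-rank among the controls: (number of
#' controls with a smaller value + half the ties) / n_controls, in \[0, 1\],
#' with 0.5 meaning typical. Bins masked in the patient map stay masked.
#'
#' @param patient_map a [vf_map()].
#' @param control_maps list of [vf_map()] sharing the patient's [map_spec()].
#' @param z_normalize standardize the maps first (default TRUE).
#' @return A [vf_map()] of kind `"rank"`.
#' @export
relative_rank_map <- function(patient_map, control_maps, z_normalize = TRUE) {
  same <- vapply(control_maps, function(m)
    identical(dim(m$values), dim(patient_map$values)), TRUE)
  if (!all(same)) stop("all maps must share the patient's grid")
  if (z_normalize) {
    patient_map <- z_normalize_map(patient_map)
    control_maps <- lapply(control_maps, z_normalize_map)
  }
  pv <- patient_map$values
  cv <- vapply(control_maps, function(m) m$values,
               matrix(0, nrow(pv), ncol(pv)))
  smaller <- rowSums(sweep(cv, c(1, 2), pv, "<"), dims = 2, na.rm = TRUE)
  ties <- rowSums(sweep(cv, c(1, 2), pv, "=="), dims = 2, na.rm = TRUE)
  nfin <- rowSums(!is.na(cv), dims = 2)
  vals <- (smaller + ties / 2) / pmax(nfin, 1)
  vals[is.na(pv) | nfin == 0] <- NA_real_
  vf_map(vals, patient_map$spec, "rank", provenance = patient_map$provenance)
}

#' Perimetry-aligned binned map and sensitivity correlation
#'
#' Bins gaze-relative positions (or VP records) into the 6-degree cells
#' centered on the HFA test locations of `field`'s layout, pairs each
#' location's value (proportion of fixations, or mean VP) with its dB
#' sensitivity, and correlates the two with [pearson_r()]. Blind-spot
#' locations are excluded.
#'
#' @param points data.frame with positions (`dx`,`dy` or `x`,`y`).
#' @param field a [sensitivity_field()].
#' @param value `"proportion"` or `"mean_vp"`.
#' @param vp VP values per point (required for `"mean_vp"`).
#' @return list: `locations` (data.frame with per-location value and dB),
#'   `r`, `n_locations`.
#' @export
binned_map_vs_sensitivity <- function(points, field,
                                      value = c("proportion", "mean_vp"),
                                      vp = NULL) {
  value <- match.arg(value)
  P <- as_points(points)
  loc <- field[!field$blind_spot, , drop = FALSE]
  half <- 3  # 6-deg cells centered on the test locations
  val <- vapply(seq_len(nrow(loc)), function(i) {
    inbin <- P[, 1] >= loc$x_deg[i] - half & P[, 1] < loc$x_deg[i] + half &
      P[, 2] >= loc$y_deg[i] - half & P[, 2] < loc$y_deg[i] + half
    if (value == "proportion") sum(inbin) / max(1, nrow(P))
    else if (any(inbin & is.finite(vp))) mean(vp[inbin], na.rm = TRUE)
    else NA_real_
  }, 0)
  ok <- is.finite(val) & is.finite(loc$sensitivity_db)
  r <- if (sum(ok) >= 3) suppressWarnings(pearson_r(val[ok], loc$sensitivity_db[ok]))
  else NA_real_
  list(locations = data.frame(location_id = loc$location_id, x_deg = loc$x_deg,
                              y_deg = loc$y_deg, value = val,
                              sensitivity_db = loc$sensitivity_db),
       r = r, n_locations = sum(ok))
}
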