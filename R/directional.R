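#' Directional saccade-amplitude profile
#'
#' Bins a participant's saccades into 18 directional bins of 20 degrees
#' (bin b covers `[20b, 20(b+1))`, b = 0..17) and records the median and
#' maximum amplitude and the count per bin. Empty bins carry NA, not zero.
#'
#' @param saccades data.frame with `amplitude` (deg) and `direction` (deg in
#'   \[0, 360)).
#' @return data.frame of class `directional_profile`: `bin`, `dir_lo`,
#'   `dir_hi`, `n`, `median_amp`, `max_amp`.
#' @export
directional_profile <- function(saccades) {
  b <- floor((saccades$direction %% 360) / 20)
  out <- data.frame(bin = 0:17, dir_lo = 20 * (0:17), dir_hi = 20 * (1:18),
                    n = 0L, median_amp = NA_real_, max_amp = NA_real_)
  for (k in 0:17) {
    amp <- saccades$amplitude[b == k]
    amp <- amp[is.finite(amp)]
    out$n[k + 1] <- length(amp)
    if (length(amp)) {
      out$median_amp[k + 1] <- stats::median(amp)
      out$max_amp[k + 1] <- max(amp)
    }
  }
  structure(out, class = c("directional_profile", "data.frame"))
}

mid_rank <- function(value, pool) {
  pool <- pool[is.finite(pool)]
  if (!length(pool) || !is.finite(value)) return(NA_real_)
  (sum(pool < value) + sum(pool == value) / 2) / length(pool)
}

#' Normalized directional rank profile of a patient against controls
#'
#' Per directional bin, ranks the patient's median and maximum saccade
#' amplitude within the control cohort: rank = (number of controls with a
#' strictly smaller value + half the number of ties) / n_controls, giving a
#' value in \[0, 1\] that is uniform under exchangeability. Ranks in the
#' extreme tails (< 0.025 or > 0.975) are flagged. Controls with an undefined
#' value in a bin are excluded from that bin's pool; bins where the patient
#' is undefined get NA.
#'
#' @param patient a [directional_profile()].
#' @param controls list of [directional_profile()] (>= 5).
#' @return data.frame of class `rank_profile`: `bin`, `dir_lo`,
#'   `median_rank`, `max_rank`, `flag_low`, `flag_high` (flags refer to the
#'   median rank; `flag_low_max`/`flag_high_max` to the maximum rank).
#' @export
normalized_rank_profile <- function(patient, controls) {
  if (length(controls) < 5) stop("need at least 5 control profiles")
  med_pool <- sapply(controls, function(p) p$median_amp)  # 18 x n
  max_pool <- sapply(controls, function(p) p$max_amp)
  mr <- vapply(1:18, function(i) mid_rank(patient$median_amp[i], med_pool[i, ]), 0)
  xr <- vapply(1:18, function(i) mid_rank(patient$max_amp[i], max_pool[i, ]), 0)
  structure(data.frame(bin = 0:17, dir_lo = 20 * (0:17),
                       median_rank = mr, max_rank = xr,
                       flag_low = !is.na(mr) & mr < 0.025,
                       flag_high = !is.na(mr) & mr > 0.975,
                       flag_low_max = !is.na(xr) & xr < 0.025,
                       flag_high_max = !is.na(xr) & xr > 0.975),
            class = c("rank_profile", "data.frame"))
}

#' Grid extent covering the control cohort's saccades
#'
#' Derives the rectangular visual-field grid half-angles from the control
#' cohort: per directional bin, the group median of the per-control median
#' amplitudes plus two standard deviations (over controls); the horizontal
#' half-angle is the maximum over the horizontal-facing bins (bin centers
#' within 45 degrees of the horizontal axis), the vertical half-angle the
#' maximum over the remaining bins. Both are rounded up to whole bin
#' multiples of the target map bin size.
#'
#' @param controls list of [directional_profile()] (>= 2).
#' @param bin_size map bin size in degrees used for snapping (default 2).
#' @return list with `half_x`, `half_y` (deg, snapped), the raw (unsnapped)
#'   values, and the bin classification.
#' @export
control_extent <- function(controls, bin_size = 2) {
  stopifnot(length(controls) >= 2)
  med <- sapply(controls, function(p) p$median_amp)  # 18 x n
  per_bin <- apply(med, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) return(NA_real_)
    stats::median(v) + 2 * stats::sd(v)
  })
  centers <- 20 * (0:17) + 10
  ang <- pmin(centers %% 180, 180 - centers %% 180)  # angle to horizontal axis
  horizontal <- ang <= 45
  snap <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_real_)
    ceiling(max(v) / bin_size) * bin_size
  }
  list(half_x = snap(per_bin[horizontal]), half_y = snap(per_bin[!horizontal]),
       raw_x = suppressWarnings(max(per_bin[horizontal], na.rm = TRUE)),
       raw_y = suppressWarnings(max(per_bin[!horizontal], na.rm = TRUE)),
       horizontal_bins = which(horizontal) - 1L,
       target_shape = "21 x 11 deg half-angle (reference study grid)")
}

#' Export a rank profile as CSV
#'
#' @param profile a [normalized_rank_profile()] result.
#' @param path output CSV.
#' @export
write_rank_profile <- function(profile, path) {
  utils::write.csv(data.frame(bin_start_deg = profile$dir_lo,
                              median_rank = profile$median_rank,
                              max_rank = profile$max_rank,
                              flag_low = profile$flag_low,
                              flag_high = profile$flag_high),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
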