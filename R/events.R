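#' Event-detection parameters
#'
#' Velocity/acceleration thresholds for classifying gaze samples into
#' saccades, matching the EyeLink parser's defaults: a sample belongs to a
#' saccade when instantaneous velocity exceeds 30 deg/s or acceleration
#' exceeds 8,000 deg/s^2 (sustained over at least two samples); everything
#' else is fixation.
#'
#' @param velocity_threshold deg/s (default 30).
#' @param acceleration_threshold deg/s^2 (default 8000).
#' @param min_fix_duration ms; fixation segments shorter than this are
#'   absorbed into the adjacent saccade to suppress detection jitter
#'   (default 40).
#' @return An object of class `event_detection_params`.
#' @export
event_detection_params <- function(velocity_threshold = 30,
                                   acceleration_threshold = 8000,
                                   min_fix_duration = 40) {
  stopifnot(velocity_threshold > 0, acceleration_threshold > 0,
            min_fix_duration >= 0)
  structure(list(velocity_threshold = velocity_threshold,
                 acceleration_threshold = acceleration_threshold,
                 min_fix_duration = min_fix_duration),
            class = "event_detection_params")
}

#' Detect fixations and saccades in raw gaze samples
#'
#' Velocity is computed with a 3-sample central difference (no additional
#' smoothing); acceleration as the central difference of speed. A sample is a
#' saccade sample when velocity or acceleration exceeds its threshold and the
#' excursion is sustained over at least two samples. Contiguous runs become
#' events; runs are split at gaps (NA samples), which are reported. Events
#' are non-overlapping and, together with gaps, exactly tile the sampled
#' span: each event covers `[t_first, t_after_last)` so durations sum to
#' `n * dt`.
#'
#' @param samples data.frame with columns `t` (ms, uniformly sampled), `x`,
#'   `y` (deg, screen-centered). NA positions mark gaps.
#' @param params an [event_detection_params()].
#' @return list with `fixations`, `saccades` (schemas as in
#'   [event_trial()]), and `gaps` (data.frame of onset/offset ms).
#' @export
detect_events <- function(samples, params = event_detection_params()) {
  empty <- function() list(
    fixations = data.frame(onset = numeric(), offset = numeric(),
                           duration = numeric(), x = numeric(), y = numeric()),
    saccades = data.frame(onset = numeric(), offset = numeric(),
                          duration = numeric(), x0 = numeric(), y0 = numeric(),
                          x1 = numeric(), y1 = numeric(), amplitude = numeric(),
                          direction = numeric(), peak_velocity = numeric()),
    gaps = data.frame(onset = numeric(), offset = numeric()))
  t <- samples$t; x <- samples$x; y <- samples$y
  n <- length(t)
  valid <- is.finite(x) & is.finite(y)
  if (n && !any(valid)) stop("data error: all gaze samples are NA")
  if (sum(valid) < 2) {
    warning("fewer than 2 valid samples; returning empty result")
    return(empty())
  }
  dt <- stats::median(diff(t))
  # central-difference speed; forward/backward at the ends
  v <- rep(NA_real_, n)
  i <- 2:(n - 1)
  v[i] <- sqrt((x[i + 1] - x[i - 1])^2 + (y[i + 1] - y[i - 1])^2) / (2 * dt) * 1000
  v[1] <- sqrt((x[2] - x[1])^2 + (y[2] - y[1])^2) / dt * 1000
  v[n] <- sqrt((x[n] - x[n - 1])^2 + (y[n] - y[n - 1])^2) / dt * 1000
  a <- rep(0, n)
  a[i] <- (v[i + 1] - v[i - 1]) / (2 * dt) * 1000
  sac <- (v > params$velocity_threshold) | (abs(a) > params$acceleration_threshold)
  sac[!valid | is.na(sac)] <- FALSE
  # require the excursion to be sustained over >= 2 samples
  r <- rle(sac)
  r$values[r$values & r$lengths < 2] <- FALSE
  sac <- inverse.rle(r)

  lab <- ifelse(valid, ifelse(sac, "S", "F"), "G")
  # absorb fixation runs shorter than min_fix_duration into adjacent saccades
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (r$values[k] != "F") next
    dur <- r$lengths[k] * dt
    if (dur >= params$min_fix_duration) next
    prev_s <- k > 1 && r$values[k - 1] == "S"
    next_s <- k < length(r$values) && r$values[k + 1] == "S"
    if (prev_s || next_s) lab[starts[k]:ends[k]] <- "S"
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  # event spans [t[start], t[end] + dt): durations tile the sampled span
  t_on <- t[starts]
  t_off <- ifelse(ends == n, t[n] + dt, t[ends + 1])
  fix <- which(r$values == "F")
  sacc <- which(r$values == "S")
  gap <- which(r$values == "G")
  fixations <- data.frame(
    onset = t_on[fix], offset = t_off[fix], duration = t_off[fix] - t_on[fix],
    x = vapply(fix, function(k) mean(x[starts[k]:ends[k]]), 0),
    y = vapply(fix, function(k) mean(y[starts[k]:ends[k]]), 0))
  x0 <- x[starts[sacc]]; y0 <- y[starts[sacc]]
  x1 <- x[ends[sacc]]; y1 <- y[ends[sacc]]
  saccades <- data.frame(
    onset = t_on[sacc], offset = t_off[sacc], duration = t_off[sacc] - t_on[sacc],
    x0 = x0, y0 = y0, x1 = x1, y1 = y1,
    amplitude = sqrt((x1 - x0)^2 + (y1 - y0)^2),
    direction = saccade_direction(x1 - x0, y1 - y0),
    peak_velocity = vapply(sacc, function(k) max(v[starts[k]:ends[k]]), 0))
  gaps <- data.frame(onset = t_on[gap], offset = t_off[gap])
  list(fixations = fixations, saccades = saccades, gaps = gaps)
}

#' Gaze-relative (visual-field) fixation vectors
#'
#' Re-expresses each fixation transition in the coordinate frame centered on
#' the preceding fixation: vector i is `position(i+1) - position(i)` in
#' degrees, so leftward and downward components are negative.
#'
#' @param fixations data.frame with `x`, `y` (deg), time-ordered.
#' @return data.frame with columns `dx`, `dy` (one row per transition; empty
#'   for fewer than 2 fixations).
#' @export
to_vf_vectors <- function(fixations) {
  n <- nrow(fixations)
  if (n < 2) return(data.frame(dx = numeric(), dy = numeric()))
  data.frame(dx = diff(fixations$x), dy = diff(fixations$y))
}

#' Basic per-participant eye-movement features
#'
#' Pools all of one participant's trials and summarizes fixation duration,
#' fixation count, saccade amplitude and saccade peak velocity. Both the
#' median (default reporting path) and mean summaries are returned.
#'
#' @param trials list of [event_trial()] for one participant.
#' @return one-row data.frame: `participant`, `n_fixations`,
#'   `fix_duration_ms`, `sacc_amplitude_deg`, `sacc_velocity_dps` (medians)
#'   and the corresponding `*_mean` columns. Saccade features are NA when the
#'   participant made no saccades.
#' @export
basic_features <- function(trials) {
  stopifnot(length(trials) >= 1)
  fd <- unlist(lapply(trials, function(tr) tr$fixations$duration))
  sa <- unlist(lapply(trials, function(tr) tr$saccades$amplitude))
  sv <- unlist(lapply(trials, function(tr) tr$saccades$peak_velocity))
  if (!length(fd)) stop("participant has no fixations")
  msum <- function(v, f) if (length(v)) f(v, na.rm = TRUE) else NA_real_
  data.frame(participant = trials[[1]]$participant,
             n_fixations = length(fd),
             fix_duration_ms = msum(fd, stats::median),
             sacc_amplitude_deg = msum(sa, stats::median),
             sacc_velocity_dps = msum(sv, stats::median),
             fix_duration_ms_mean = msum(fd, mean),
             sacc_amplitude_deg_mean = msum(sa, mean),
             sacc_velocity_dps_mean = msum(sv, mean))
}

#' Two-sample rank-sum comparison of groups
#'
#' Two-sided Wilcoxon-Mann-Whitney rank-sum test (exact when sample sizes
#' permit and there are no ties) with a z statistic from the tie-corrected
#' normal approximation, and a Bonferroni-corrected significance level
#' `0.05 / n_comparisons` rounded to three decimals as conventionally
#' reported (4 comparisons -> 0.013; 3 -> 0.017).
#'
#' @param values_a,values_b numeric vectors (each length >= 2).
#' @param n_comparisons number of tests corrected for (default 1).
#' @return list of class `group_comparison`: medians and SDs per group, `U`,
#'   `z`, `p`, `n_comparisons`, `corrected_alpha`, `significant`.
#' @export
compare_groups <- function(values_a, values_b, n_comparisons = 1) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  n1 <- length(values_a); n2 <- length(values_b)
  U <- unname(wt$statistic)
  # tie-corrected normal approximation for z
  ranks <- rank(c(values_a, values_b))
  nt <- table(ranks)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1)))
  z <- if (sigma2 > 0) (U - n1 * n2 / 2) / sqrt(sigma2) else 0
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  alpha <- round(0.05 / n_comparisons, 3)
  structure(list(median_a = stats::median(values_a), sd_a = stats::sd(values_a),
                 median_b = stats::median(values_b), sd_b = stats::sd(values_b),
                 U = U, z = z, p = p, n_comparisons = n_comparisons,
                 corrected_alpha = alpha, significant = p < alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("rank-sum: medians %.4g vs %.4g, U = %g, z = %.3f, p = %.4g (alpha = %g)%s\n",
              x$median_a, x$median_b, x$U, x$z, x$p, x$corrected_alpha,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Pearson correlation with degenerate-input guard
#'
#' @param x,y numeric vectors of equal length (>= 3), pairwise-complete.
#' @return correlation coefficient in \[-1, 1\], or NA with a warning when
#'   either input has zero variance.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) { warning("fewer than 3 complete pairs"); return(NA_real_) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}
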