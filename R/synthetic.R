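#' Synthetic perimetry field by defect archetype
#'
#' Builds a sensitivity field from an age-normal baseline of 30 dB plus
#' measurement noise, attenuated toward 0 dB inside the archetype's defect
#' region in proportion to `severity`:
#' \describe{
#'   \item{normal}{no defect.}
#'   \item{peripheral}{eccentricity beyond 10 deg (scotoma outside the
#'     central 10 deg).}
#'   \item{nasal_arc}{nasal half-field arc (x <= -9 deg in right-eye
#'     orientation).}
#'   \item{tunnel}{everything beyond `tunnel_radius` (default 10 deg);
#'     the central island stays intact.}
#'   \item{central}{eccentricity within 10 deg.}
#'   \item{blind}{the whole field.}
#' }
#'
#' @param archetype defect type (see above).
#' @param severity in \[0, 1\]; 1 drives the region to 0 dB.
#' @param layout `"hfa24_2"` or `"hfa30_2"`.
#' @param seed RNG seed for the measurement noise.
#' @param noise_sd per-location noise SD in dB (default 1).
#' @param tunnel_radius intact central radius for `tunnel` (deg).
#' @param baseline age-normal sensitivity in dB (default 30).
#' @param eye stored orientation tag.
#' @return A [sensitivity_field()] with MD = mean(sensitivity) - baseline.
#' @export
make_field <- function(archetype = c("normal", "peripheral", "nasal_arc",
                                     "tunnel", "central", "blind"),
                       severity = 1, layout = c("hfa24_2", "hfa30_2"),
                       seed = 1L, noise_sd = 1, tunnel_radius = 10,
                       baseline = 30, eye = "right") {
  archetype <- match.arg(archetype)
  layout <- match.arg(layout)
  stopifnot(severity >= 0, severity <= 1)
  loc <- hfa_locations(layout)
  ecc <- sqrt(loc$x_deg^2 + loc$y_deg^2)
  region <- switch(archetype,
    normal = rep(FALSE, nrow(loc)),
    peripheral = ecc > 10,
    nasal_arc = loc$x_deg <= -9,
    tunnel = ecc > tunnel_radius,
    central = ecc <= 10,
    blind = rep(TRUE, nrow(loc)))
  s <- rep(baseline, nrow(loc))
  s[region] <- baseline * (1 - severity)
  if (noise_sd > 0)
    s <- s + with_seed(seed, stats::rnorm(nrow(loc), 0, noise_sd))
  s <- pmax(0, s)
  md <- mean(s[!loc$blind_spot]) - baseline
  f <- sensitivity_field(s, layout, md = md, eye = eye)
  attr(f, "archetype") <- archetype
  attr(f, "severity") <- severity
  f
}

#' Synthetic time-varying salience track
#'
#' Stands in for video content: a single salient target whose position is
#' piecewise constant, jumping at Poisson-process times to a uniform position
#' inside an inset screen box. Controls that follow the track produce the
#' shared, time-locked gaze behavior that the viewing-priority statistic
#' rewards.
#'
#' @param duration_s clip duration in seconds.
#' @param jump_rate expected jumps per second (Poisson; default 0.5).
#' @param spread half-extents `c(x, y)` in degrees of the box the target
#'   occupies (default `c(18, 13)`, inset from the reference screen).
#' @param seed RNG seed.
#' @param clip clip identifier.
#' @return An object of class `salience_track` with a `segments` data.frame
#'   (`t_start_ms`, `x`, `y`).
#' @export
make_track <- function(duration_s, jump_rate = 0.5, spread = c(18, 13),
                       seed = 1L, clip = "clip1") {
  stopifnot(duration_s > 0, jump_rate >= 0)
  seg <- with_seed(seed, {
    n_jumps <- if (jump_rate > 0) stats::rpois(1, jump_rate * duration_s) else 0L
    t_start <- c(0, sort(stats::runif(n_jumps, 0, duration_s * 1000)))
    data.frame(t_start_ms = t_start,
               x = stats::runif(n_jumps + 1, -spread[1], spread[1]),
               y = stats::runif(n_jumps + 1, -spread[2], spread[2]))
  })
  structure(list(clip = clip, duration_s = duration_s, segments = seg,
                 spread = spread, jump_rate = jump_rate),
            class = "salience_track")
}

track_position <- function(track, t_ms) {
  i <- findInterval(t_ms, track$segments$t_start_ms)
  i[i < 1] <- 1
  cbind(track$segments$x[i], track$segments$y[i])
}

#' Simulated observer model
#'
#' Parameters of the scanpath generator. Two mechanisms shape patient gaze:
#' bottom-up loss (the salient target is only followed when it is detected,
#' and detection probability falls with the field sensitivity at the
#' target's gaze-relative location) and an optional top-down compensation
#' (gaze deliberately biased into the damaged field).
#'
#' @param p_follow probability of saccading to the target once detected
#'   (default 0.8).
#' @param center_bias_weight fraction by which each exploratory saccade pulls
#'   the gaze back toward the screen center (default 0.3).
#' @param center_bias_sd SD in degrees of the exploratory saccade step
#'   (default 2.5): when the target is not followed, the next gaze position
#'   is `(1 - weight) * gaze + N(0, sd)` per axis, keeping exploratory
#'   saccades small and center-clustered.
#' @param fix_dur_median,fix_dur_sdlog log-normal fixation-duration
#'   parameters (median 280 ms, sigma 0.4).
#' @param follow_min_dist minimum gaze-to-target distance in degrees for a
#'   following saccade (default 2): a target already fixated triggers
#'   exploration instead of a micro-refixation.
#' @param landing_sd saccade landing noise SD in degrees (default 1).
#' @param vmax,msc main-sequence parameters: peak velocity =
#'   `vmax * (1 - exp(-amplitude / msc))`, defaults 500 deg/s and 5 deg.
#' @param compensation probability in \[0, 1\] of a compensatory saccade into
#'   the damaged field when the target was not followed (default 0).
#' @param detect_slope,detect_mid logistic detection curve
#'   `p = plogis(detect_slope * (dB - detect_mid))`; defaults give p ~ 0.98
#'   at 30 dB and ~ 0.3 at 10 dB.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(p_follow = 0.8, center_bias_weight = 0.3,
                           center_bias_sd = 2.5, follow_min_dist = 2,
                           fix_dur_median = 280, fix_dur_sdlog = 0.4,
                           landing_sd = 1, vmax = 500, msc = 5,
                           compensation = 0,
                           detect_slope = 0.23695, detect_mid = 13.575) {
  stopifnot(p_follow >= 0, p_follow <= 1, center_bias_sd > 0,
            center_bias_weight >= 0, center_bias_weight <= 1,
            compensation >= 0, compensation <= 1)
  structure(list(p_follow = p_follow, center_bias_weight = center_bias_weight,
                 center_bias_sd = center_bias_sd,
                 follow_min_dist = follow_min_dist,
                 fix_dur_median = fix_dur_median, fix_dur_sdlog = fix_dur_sdlog,
                 landing_sd = landing_sd, vmax = vmax, msc = msc,
                 compensation = compensation, detect_slope = detect_slope,
                 detect_mid = detect_mid), class = "observer_model")
}

field_sensitivity_at <- function(field, dx, dy) {
  # nearest test location; constant extrapolation beyond the grid
  i <- which.min((field$x_deg - dx)^2 + (field$y_deg - dy)^2)
  field$sensitivity_db[i]
}

default_geometry <- function() screen_geometry(1920, 1080, 50, 35, 60)

#' Simulate one free-viewing trial
#'
#' Alternates fixations and saccades: after each fixation the observer either
#' follows the salience track (if the target was detected through their
#' sensitivity field at its current gaze-relative location), makes a
#' compensatory saccade into the damaged field, or relocates under center
#' bias. Saccade peak velocity comes from the main sequence. The emitted
#' trial uses the same event schema as [read_event_table()]; the ground-truth
#' event log is attached as `attr(, "truth")`.
#'
#' @param track a [make_track()].
#' @param field a [sensitivity_field()] (the effective viewing field:
#'   monocular tested-eye field or binocular IVF). NULL means an intact
#'   field.
#' @param model an [observer_model()].
#' @param participant,clip identifiers.
#' @param seed RNG seed.
#' @param geometry a [screen_geometry()].
#' @return An [event_trial()].
#' @export
simulate_trial <- function(track, field = NULL, model = observer_model(),
                           participant = "sim", clip = track$clip, seed = 1L,
                           geometry = default_geometry()) {
  if (is.null(field)) field <- make_field("normal", 0, seed = seed, noise_sd = 0)
  ext <- screen_extent_deg(geometry) - 0.5
  damaged <- which(field$sensitivity_db < 20 & !field$blind_spot)
  dur_ms <- track$duration_s * 1000
  mul <- log(model$fix_dur_median)
  with_seed(seed, {
    t <- 0; gx <- 0; gy <- 0
    fx <- list(); sc <- list()
    repeat {
      fdur <- stats::rlnorm(1, mul, model$fix_dur_sdlog)
      f_off <- min(t + fdur, dur_ms)
      fx[[length(fx) + 1]] <- c(t, f_off, gx, gy)
      t <- f_off
      if (t >= dur_ms) break
      tp <- track_position(track, t)
      s_db <- field_sensitivity_at(field, tp[1] - gx, tp[2] - gy)
      detected <- stats::runif(1) < stats::plogis(model$detect_slope * (s_db - model$detect_mid))
      far_enough <- sqrt((tp[1] - gx)^2 + (tp[2] - gy)^2) >= model$follow_min_dist
      if (detected && far_enough && stats::runif(1) < model$p_follow) {
        nx <- tp[1] + stats::rnorm(1, 0, model$landing_sd)
        ny <- tp[2] + stats::rnorm(1, 0, model$landing_sd)
      } else if (length(damaged) && stats::runif(1) < model$compensation) {
        j <- if (length(damaged) == 1) damaged else sample(damaged, 1)
        nx <- gx + field$x_deg[j] + stats::rnorm(1, 0, model$landing_sd)
        ny <- gy + field$y_deg[j] + stats::rnorm(1, 0, model$landing_sd)
      } else {
        nx <- (1 - model$center_bias_weight) * gx +
          stats::rnorm(1, 0, model$center_bias_sd)
        ny <- (1 - model$center_bias_weight) * gy +
          stats::rnorm(1, 0, model$center_bias_sd)
      }
      nx <- max(-ext[1], min(ext[1], nx))
      ny <- max(-ext[2], min(ext[2], ny))
      amp <- sqrt((nx - gx)^2 + (ny - gy)^2)
      sdur <- max(10, 2.2 * amp + 21)
      s_off <- min(t + sdur, dur_ms)
      pv <- model$vmax * (1 - exp(-amp / model$msc))
      sc[[length(sc) + 1]] <- c(t, s_off, gx, gy, nx, ny, amp,
                                saccade_direction(nx - gx, ny - gy), pv)
      t <- s_off
      gx <- nx; gy <- ny
      if (t >= dur_ms) break
    }
    fdf <- as.data.frame(do.call(rbind, fx))
    names(fdf) <- c("onset", "offset", "x", "y")
    fdf$duration <- fdf$offset - fdf$onset
    fdf <- fdf[, c("onset", "offset", "duration", "x", "y")]
    if (length(sc)) {
      sdf <- as.data.frame(do.call(rbind, sc))
      names(sdf) <- c("onset", "offset", "x0", "y0", "x1", "y1", "amplitude",
                      "direction", "peak_velocity")
      sdf$duration <- sdf$offset - sdf$onset
      sdf <- sdf[, c("onset", "offset", "duration", "x0", "y0", "x1", "y1",
                     "amplitude", "direction", "peak_velocity")]
    } else {
      sdf <- data.frame(onset = numeric(), offset = numeric(), duration = numeric(),
                        x0 = numeric(), y0 = numeric(), x1 = numeric(),
                        y1 = numeric(), amplitude = numeric(),
                        direction = numeric(), peak_velocity = numeric())
    }
    tr <- event_trial(participant, clip, fdf, sdf, geometry)
    attr(tr, "truth") <- list(fixations = fdf, saccades = sdf)
    tr
  })
}

#' Synthesize raw gaze samples from a simulated trial
#'
#' Renders the trial's ground-truth events as a uniformly sampled gaze trace:
#' constant position during fixations and a raised-cosine (smooth bell-shaped
#' velocity) trajectory during saccades. The trial's own event log is the
#' ground truth that [detect_events()] should recover.
#'
#' @param trial an [event_trial()] from [simulate_trial()].
#' @param hz sampling rate (default 1000).
#' @return data.frame with `t` (ms), `x`, `y` (deg).
#' @export
samples_from_trial <- function(trial, hz = 1000) {
  dt <- 1000 / hz
  t_end <- max(trial$fixations$offset, trial$saccades$offset, 0)
  t <- seq(0, t_end - dt / 2, by = dt)
  x <- rep(NA_real_, length(t)); y <- rep(NA_real_, length(t))
  for (i in seq_len(nrow(trial$fixations))) {
    f <- trial$fixations[i, ]
    k <- t >= f$onset & t < f$offset
    x[k] <- f$x; y[k] <- f$y
  }
  for (i in seq_len(nrow(trial$saccades))) {
    s <- trial$saccades[i, ]
    k <- which(t >= s$onset & t < s$offset)
    if (!length(k)) next
    ph <- (t[k] - s$onset) / s$duration
    w <- (1 - cos(pi * ph)) / 2  # raised cosine: 0 -> 1
    x[k] <- s$x0 + w * (s$x1 - s$x0)
    y[k] <- s$y0 + w * (s$y1 - s$y0)
  }
  data.frame(t = t, x = x, y = y)
}

#' Cohort configuration
#'
#' @param n_controls,n_patients group sizes (default 20 each).
#' @param archetypes patient defect archetypes, recycled over patients.
#' @param severity defect severity in \[0, 1\] (recycled; default 1).
#' @param covered_severity severity of the covered/other eye's field
#'   (default 0.2: asymmetric disease).
#' @param regime `"monocular"` (simulate through the tested eye's field) or
#'   `"binocular"` (through the best-location merged IVF).
#' @param n_clips,clip_duration_s clip set (default 10 clips of 60 s).
#' @param jump_rate salience jumps per second (default 0.5).
#' @param compensation patient compensatory-gaze probability (default 0).
#' @param layout perimetry layout (default 24-2).
#' @param seed master seed; every stream is derived from it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_controls = 20, n_patients = 20,
                          archetypes = c("peripheral", "nasal_arc", "tunnel",
                                         "central", "blind"),
                          severity = 1, covered_severity = 0.2,
                          regime = c("monocular", "binocular"),
                          n_clips = 10, clip_duration_s = 60, jump_rate = 0.5,
                          compensation = 0, layout = "hfa24_2", seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_controls >= 0, n_patients >= 0, n_clips >= 1)
  structure(list(n_controls = n_controls, n_patients = n_patients,
                 archetypes = archetypes, severity = severity,
                 covered_severity = covered_severity, regime = regime,
                 n_clips = n_clips, clip_duration_s = clip_duration_s,
                 jump_rate = jump_rate, compensation = compensation,
                 layout = layout, seed = as.integer(seed)),
            class = "cohort_config")
}

derive_seed <- function(master, a, b = 0L) {
  as.integer((as.double(master) * 48271 + a * 7919 + b * 104729) %% 2147483647)
}

#' Generate a synthetic study cohort
#'
#' Builds the salience tracks, per-patient two-eye sensitivity fields
#' (tested eye at `severity`, other eye at `covered_severity`), and simulates
#' every participant's trials. Under the monocular regime patients view
#' through the tested eye's field; under the binocular regime through the
#' best-location IVF of the two eyes. Fully deterministic per master seed.
#'
#' @param config a [cohort_config()].
#' @return list of class `cohort`: `trials` (list of [event_trial()]),
#'   `tracks`, `participants` (data.frame with group, archetype, severity,
#'   md_tested, md_covered, md_diff, ivf_score), `fields` (per patient:
#'   tested/covered/ivf/effective), `control_ids`, `config`.
#' @export
make_cohort <- function(config = cohort_config()) {
  tracks <- lapply(seq_len(config$n_clips), function(c)
    make_track(config$clip_duration_s, config$jump_rate,
               seed = derive_seed(config$seed, c), clip = sprintf("clip%02d", c)))
  ids_c <- sprintf("C%03d", seq_len(config$n_controls))
  ids_p <- sprintf("P%03d", seq_len(config$n_patients))
  arch <- rep_len(config$archetypes, max(1, config$n_patients))
  sev <- rep_len(config$severity, max(1, config$n_patients))
  fields <- list()
  trials <- list()
  participants <- list()
  for (i in seq_along(ids_p)) {
    tested <- make_field(arch[i], sev[i], config$layout,
                         seed = derive_seed(config$seed, 1000L + i))
    covered <- make_field(arch[i], config$covered_severity, config$layout,
                          seed = derive_seed(config$seed, 2000L + i))
    ivf <- merge_ivf(tested, covered)
    effective <- if (config$regime == "monocular") tested else ivf
    fields[[ids_p[i]]] <- list(tested = tested, covered = covered, ivf = ivf,
                               effective = effective)
    participants[[length(participants) + 1]] <- data.frame(
      participant = ids_p[i], group = "patient", archetype = arch[i],
      severity = sev[i], md_tested = attr(tested, "md"),
      md_covered = attr(covered, "md"),
      md_diff = attr(tested, "md") - attr(covered, "md"),
      ivf_score = ivf_score(ivf))
  }
  for (id in ids_c)
    participants[[length(participants) + 1]] <- data.frame(
      participant = id, group = "control", archetype = "normal", severity = 0,
      md_tested = 0, md_covered = 0, md_diff = 0, ivf_score = 0L)
  all_ids <- c(ids_c, ids_p)
  for (pi in seq_along(all_ids)) {
    id <- all_ids[pi]
    is_pat <- id %in% ids_p
    model <- observer_model(compensation = if (is_pat) config$compensation else 0)
    field <- if (is_pat) fields[[id]]$effective else NULL
    for (c in seq_len(config$n_clips)) {
      trials[[length(trials) + 1]] <-
        simulate_trial(tracks[[c]], field, model, participant = id,
                       clip = tracks[[c]]$clip,
                       seed = derive_seed(config$seed, 3000L + pi, c))
    }
  }
  structure(list(trials = trials, tracks = tracks,
                 participants = do.call(rbind, participants),
                 fields = fields, control_ids = ids_c, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d controls, %d patients, %d clips x %g s (%s regime)\n",
              x$config$n_controls, x$config$n_patients, x$config$n_clips,
              x$config$clip_duration_s, x$config$regime))
  invisible(x)
}
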