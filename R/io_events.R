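#' Event-table dialects
#'
#' Describes how an on-disk eye-movement file maps onto the package's event
#' schema. Three dialects are supported:
#' \describe{
#'   \item{`csv_events`}{one row per tracker-parsed event. Default columns:
#'     `participant, clip, event` (`"fix"` or `"sac"`), `t_on_ms, t_off_ms`,
#'     `x, y` (fixation position, px) and `x0, y0, x1, y1, amp_deg, dir_deg,
#'     pvel` (saccades). Positions are screen pixels with a top-left origin.}
#'   \item{`eyelink_asc`}{EyeLink ASC event lines; only `EFIX`, `ESACC` and
#'     `MSG ... TRIALID <clip>` lines are interpreted.}
#'   \item{`raw_samples_csv`}{gaze samples (`participant, clip, t_ms, x, y`
#'     in px); events are produced by [detect_events()].}
#' }
#'
#' @param kind one of `"csv_events"`, `"eyelink_asc"`, `"raw_samples_csv"`.
#' @param columns optional named character vector remapping roles to column
#'   names, e.g. `c(participant = "subj")`.
#' @return An object of class `event_dialect`.
#' @export
event_dialect <- function(kind = c("csv_events", "eyelink_asc", "raw_samples_csv"),
                          columns = NULL) {
  kind <- match.arg(kind)
  default <- c(participant = "participant", clip = "clip", event = "event",
               t_on = "t_on_ms", t_off = "t_off_ms", x = "x", y = "y",
               x0 = "x0", y0 = "y0", x1 = "x1", y1 = "y1",
               amp = "amp_deg", dir = "dir_deg", pvel = "pvel",
               t = "t_ms")
  if (!is.null(columns)) default[names(columns)] <- columns
  structure(list(kind = kind, columns = default), class = "event_dialect")
}

#' A single free-viewing trial
#'
#' One participant watching one clip: time-ordered fixations and saccades in
#' screen-centered visual degrees (x right-positive, y up-positive).
#'
#' @param participant,clip identifiers.
#' @param fixations data.frame with `onset`, `offset`, `duration` (ms) and
#'   `x`, `y` (deg).
#' @param saccades data.frame with `onset`, `offset`, `duration` (ms),
#'   `x0, y0, x1, y1` (deg), `amplitude` (deg), `direction` (deg in
#'   \[0, 360)) and `peak_velocity` (deg/s).
#' @param geometry the [screen_geometry()] the positions refer to, or NULL.
#' @return An object of class `event_trial`.
#' @export
event_trial <- function(participant, clip, fixations, saccades, geometry = NULL) {
  fx <- c("onset", "offset", "duration", "x", "y")
  sx <- c("onset", "offset", "duration", "x0", "y0", "x1", "y1",
          "amplitude", "direction", "peak_velocity")
  if (!all(fx %in% names(fixations)))
    stop("fixations must have columns: ", paste(fx, collapse = ", "))
  if (!all(sx %in% names(saccades)))
    stop("saccades must have columns: ", paste(sx, collapse = ", "))
  structure(list(participant = as.character(participant),
                 clip = as.character(clip),
                 fixations = fixations, saccades = saccades,
                 geometry = geometry),
            class = "event_trial")
}

#' @export
print.event_trial <- function(x, ...) {
  cat(sprintf("event_trial: participant %s, clip %s — %d fixations, %d saccades\n",
              x$participant, x$clip, nrow(x$fixations), nrow(x$saccades)))
  invisible(x)
}

saccade_direction <- function(dx, dy) (atan2(dy, dx) * 180 / pi) %% 360

#' Read an eye-movement event table
#'
#' Parses a file in one of the supported dialects, converts positions from
#' screen pixels to screen-centered degrees via [px_to_deg()], and groups the
#' events into one [event_trial()] per (participant, clip). Saccade amplitude
#' and direction are always recomputed from the converted endpoints so they
#' satisfy the degree-space invariants regardless of what the file carried.
#'
#' @param path file path.
#' @param dialect an [event_dialect()].
#' @param geometry a [screen_geometry()].
#' @param participant participant id for dialects that do not carry one
#'   (eyelink_asc).
#' @param detect_params [event_detection_params()] used for the
#'   `raw_samples_csv` dialect.
#' @return list of [event_trial()] objects.
#' @export
read_event_table <- function(path, dialect = event_dialect(), geometry,
                             participant = NULL,
                             detect_params = event_detection_params()) {
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect$kind,
    csv_events = read_csv_events(path, dialect, geometry),
    eyelink_asc = read_eyelink_asc(path, geometry, participant),
    raw_samples_csv = read_raw_samples(path, dialect, geometry, detect_params)
  )
}

require_columns <- function(df, roles, dialect, path) {
  cols <- dialect$columns[roles]
  miss <- cols[!cols %in% names(df)]
  if (length(miss))
    stop("format error in ", path, ": missing mapped column(s) ",
         paste(miss, collapse = ", "))
  cols
}

check_monotone <- function(onsets, participant, clip) {
  if (is.unsorted(onsets))
    stop("data error: non-monotone timestamps in trial (participant ",
         participant, ", clip ", clip, ")")
}

read_csv_events <- function(path, dialect, geometry) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cl <- require_columns(df, c("participant", "clip", "event", "t_on", "t_off",
                              "x", "y"), dialect, path)
  keys <- unique(df[, cl[c("participant", "clip")]])
  trials <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df[[cl["participant"]]] == keys[i, 1] &
              df[[cl["clip"]]] == keys[i, 2], , drop = FALSE]
    check_monotone(sub[[cl["t_on"]]], keys[i, 1], keys[i, 2])
    fx <- sub[sub[[cl["event"]]] == "fix", , drop = FALSE]
    sc <- sub[sub[[cl["event"]]] == "sac", , drop = FALSE]
    pos <- px_to_deg(fx[[cl["x"]]], fx[[cl["y"]]], geometry)
    fixations <- data.frame(onset = fx[[cl["t_on"]]], offset = fx[[cl["t_off"]]],
                            duration = fx[[cl["t_off"]]] - fx[[cl["t_on"]]],
                            x = pos$x, y = pos$y)
    scl <- dialect$columns
    p0 <- px_to_deg(sc[[scl["x0"]]], sc[[scl["y0"]]], geometry)
    p1 <- px_to_deg(sc[[scl["x1"]]], sc[[scl["y1"]]], geometry)
    pvel <- if (scl["pvel"] %in% names(sc)) sc[[scl["pvel"]]] else rep(NA_real_, nrow(sc))
    saccades <- data.frame(onset = sc[[scl["t_on"]]], offset = sc[[scl["t_off"]]],
                           duration = sc[[scl["t_off"]]] - sc[[scl["t_on"]]],
                           x0 = p0$x, y0 = p0$y, x1 = p1$x, y1 = p1$y,
                           amplitude = sqrt((p1$x - p0$x)^2 + (p1$y - p0$y)^2),
                           direction = saccade_direction(p1$x - p0$x, p1$y - p0$y),
                           peak_velocity = pvel)
    event_trial(keys[i, 1], keys[i, 2], fixations, saccades, geometry)
  })
  trials
}

read_eyelink_asc <- function(path, geometry, participant) {
  if (is.null(participant)) participant <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  clip <- NA_character_
  fix <- list(); sac <- list()
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "MSG" && length(tok) >= 4 && tok[3] == "TRIALID") {
      clip <- tok[4]
    } else if (tok[1] == "EFIX" && length(tok) >= 7) {
      fix[[length(fix) + 1]] <- c(clip = clip, as.numeric(tok[3:7]))
    } else if (tok[1] == "ESACC" && length(tok) >= 11) {
      sac[[length(sac) + 1]] <- c(clip = clip, as.numeric(tok[3:11]))
    }
  }
  to_df <- function(lst, nm) {
    if (!length(lst)) return(NULL)
    m <- do.call(rbind, lst)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- c("clip", nm)
    for (v in nm) df[[v]] <- as.numeric(df[[v]])
    df
  }
  fdf <- to_df(fix, c("t_on", "t_off", "dur", "x", "y"))
  sdf <- to_df(sac, c("t_on", "t_off", "dur", "x0", "y0", "x1", "y1", "amp", "pvel"))
  clips <- unique(c(if (!is.null(fdf)) fdf$clip, if (!is.null(sdf)) sdf$clip))
  lapply(clips, function(cl) {
    f <- if (is.null(fdf)) NULL else fdf[fdf$clip == cl, , drop = FALSE]
    s <- if (is.null(sdf)) NULL else sdf[sdf$clip == cl, , drop = FALSE]
    check_monotone(if (is.null(f)) numeric() else f$t_on, participant, cl)
    pos <- px_to_deg(f$x, f$y, geometry)
    fixations <- data.frame(onset = f$t_on, offset = f$t_off,
                            duration = f$t_off - f$t_on, x = pos$x, y = pos$y)
    if (is.null(s)) {
      saccades <- data.frame(onset = numeric(), offset = numeric(),
                             duration = numeric(), x0 = numeric(), y0 = numeric(),
                             x1 = numeric(), y1 = numeric(), amplitude = numeric(),
                             direction = numeric(), peak_velocity = numeric())
    } else {
      p0 <- px_to_deg(s$x0, s$y0, geometry)
      p1 <- px_to_deg(s$x1, s$y1, geometry)
      saccades <- data.frame(onset = s$t_on, offset = s$t_off,
                             duration = s$t_off - s$t_on,
                             x0 = p0$x, y0 = p0$y, x1 = p1$x, y1 = p1$y,
                             amplitude = sqrt((p1$x - p0$x)^2 + (p1$y - p0$y)^2),
                             direction = saccade_direction(p1$x - p0$x, p1$y - p0$y),
                             peak_velocity = s$pvel)
    }
    event_trial(participant, cl, fixations, saccades, geometry)
  })
}

read_raw_samples <- function(path, dialect, geometry, params) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cl <- require_columns(df, c("participant", "clip", "t", "x", "y"), dialect, path)
  keys <- unique(df[, cl[c("participant", "clip")]])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df[[cl["participant"]]] == keys[i, 1] &
              df[[cl["clip"]]] == keys[i, 2], , drop = FALSE]
    check_monotone(sub[[cl["t"]]], keys[i, 1], keys[i, 2])
    pos <- px_to_deg(sub[[cl["x"]]], sub[[cl["y"]]], geometry)
    ev <- detect_events(data.frame(t = sub[[cl["t"]]], x = pos$x, y = pos$y), params)
    event_trial(keys[i, 1], keys[i, 2], ev$fixations, ev$saccades, geometry)
  })
}

#' Write trials to a csv_events file
#'
#' Inverse of [read_event_table()] for the `csv_events` dialect: degree
#' positions are converted back to top-left-origin screen pixels, so the file
#' is schema-identical to real tracker exports.
#'
#' @param trials list of [event_trial()].
#' @param path output file.
#' @param geometry a [screen_geometry()]; defaults to the first trial's.
#' @export
write_event_table <- function(trials, path, geometry = NULL) {
  if (is.null(geometry)) geometry <- trials[[1]]$geometry
  rows <- lapply(trials, function(tr) {
    fpx <- deg_to_px(tr$fixations$x, tr$fixations$y, geometry)
    f <- data.frame(participant = tr$participant, clip = tr$clip, event = "fix",
                    t_on_ms = tr$fixations$onset, t_off_ms = tr$fixations$offset,
                    x = fpx$x, y = fpx$y, x0 = NA_real_, y0 = NA_real_,
                    x1 = NA_real_, y1 = NA_real_, amp_deg = NA_real_,
                    dir_deg = NA_real_, pvel = NA_real_)
    p0 <- deg_to_px(tr$saccades$x0, tr$saccades$y0, geometry)
    p1 <- deg_to_px(tr$saccades$x1, tr$saccades$y1, geometry)
    s <- data.frame(participant = tr$participant, clip = tr$clip, event = "sac",
                    t_on_ms = tr$saccades$onset, t_off_ms = tr$saccades$offset,
                    x = NA_real_, y = NA_real_, x0 = p0$x, y0 = p0$y,
                    x1 = p1$x, y1 = p1$y, amp_deg = tr$saccades$amplitude,
                    dir_deg = tr$saccades$direction, pvel = tr$saccades$peak_velocity)
    out <- rbind(f, s)
    out[order(out$t_on_ms), , drop = FALSE]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
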