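#' Pipeline run configuration
#'
#' Exactly one input source: either `events_path` (+ `perimetry` paths) for
#' real data, or `simulate = TRUE` with a [cohort_config()] for the bundled
#' generator.
#'
#' @param out_dir output directory (created if missing).
#' @param simulate use the synthetic cohort generator.
#' @param cohort a [cohort_config()] when simulating.
#' @param events_path csv_events file when not simulating.
#' @param geometry a [screen_geometry()] for reading real events.
#' @param control_ids participant ids forming the control group (required for
#'   real data; inferred for synthetic cohorts).
#' @param regime `"monocular"` or `"binocular"` (reporting tag).
#' @param analyses which stages to run.
#' @param seed seed for every stochastic stage.
#' @param vp a [vp_params()].
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, simulate = TRUE, cohort = cohort_config(),
                       events_path = NULL, geometry = default_geometry(),
                       control_ids = NULL, regime = c("monocular", "binocular"),
                       analyses = c("features", "directions", "vp", "maps",
                                    "classify", "ivf"),
                       seed = 1L, vp = vp_params()) {
  regime <- match.arg(regime)
  if (simulate && !is.null(events_path))
    stop("exactly one input source: simulate or events_path")
  if (!simulate && is.null(events_path))
    stop("exactly one input source: supply events_path or set simulate = TRUE")
  structure(list(out_dir = out_dir, simulate = simulate, cohort = cohort,
                 events_path = events_path, geometry = geometry,
                 control_ids = control_ids, regime = regime,
                 analyses = analyses, seed = as.integer(seed), vp = vp),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [run_config()] arguments; `geometry` and
#' `cohort` are nested maps passed to [screen_geometry()] and
#' [cohort_config()].
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  geom <- if (!is.null(y$geometry)) do.call(screen_geometry, y$geometry)
  else default_geometry()
  coh <- if (!is.null(y$cohort)) do.call(cohort_config, y$cohort)
  else cohort_config()
  run_config(out_dir = y$out_dir,
             simulate = isTRUE(y$simulate) || is.null(y$events_path),
             cohort = coh, events_path = y$events_path, geometry = geom,
             control_ids = y$control_ids,
             regime = if (is.null(y$regime)) "monocular" else y$regime,
             analyses = if (is.null(y$analyses))
               c("features", "directions", "vp", "maps", "classify", "ivf")
             else y$analyses,
             seed = if (is.null(y$seed)) 1L else y$seed)
}

features_by_participant <- function(trials) {
  ids <- unique(vapply(trials, function(tr) tr$participant, ""))
  do.call(rbind, lapply(ids, function(id)
    basic_features(trials[vapply(trials, function(tr) tr$participant, "") == id])))
}

#' Per-participant fixation maps on a control-derived grid
#'
#' Builds, per participant and clip, the count-based fixation map in
#' gaze-relative coordinates on the grid sized by [control_extent()] from the
#' control cohort's directional profiles.
#'
#' @param trials list of [event_trial()].
#' @param control_ids control participant ids.
#' @param bin bin size in degrees (default 2).
#' @return list: `maps` (per participant: list per clip of [vf_map()]),
#'   `spec`, `extent`.
#' @export
cohort_fixation_maps <- function(trials, control_ids, bin = 2) {
  parts <- vapply(trials, function(tr) tr$participant, "")
  profs <- lapply(unique(parts[parts %in% control_ids]), function(id) {
    sacc <- do.call(rbind, lapply(trials[parts == id], function(tr) tr$saccades))
    directional_profile(sacc)
  })
  ext <- control_extent(profs, bin_size = bin)
  spec <- map_spec(max(ext$half_x, bin), max(ext$half_y, bin), bin = bin)
  ids <- unique(parts)
  maps <- lapply(ids, function(id) {
    tr_id <- trials[parts == id]
    clips <- vapply(tr_id, function(tr) tr$clip, "")
    out <- lapply(tr_id, function(tr) count_map(to_vf_vectors(tr$fixations), spec,
                                                normalize = "max"))
    names(out) <- clips
    out
  })
  names(maps) <- ids
  list(maps = maps, spec = spec, extent = ext)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages on synthetic or real event data and writes
#' every result family to `out_dir`: per-participant feature tables,
#' directional rank profiles, per-fixation VP records, fixation/VP maps,
#' kernel-PCA embeddings with naive-Bayes accuracies, IVF scores, and a JSON
#' summary (group medians, rank-sum z and p, corrected alphas, correlations).
#' Identical config + seed yields identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(regime = config$regime, seed = config$seed)
  if (config$simulate) {
    coh <- make_cohort(config$cohort)
    trials <- coh$trials
    control_ids <- coh$control_ids
    participants <- coh$participants
    fields <- coh$fields
  } else {
    trials <- read_event_table(config$events_path, event_dialect("csv_events"),
                               config$geometry)
    control_ids <- config$control_ids
    if (is.null(control_ids)) stop("control_ids required for real event data")
    ids <- unique(vapply(trials, function(tr) tr$participant, ""))
    participants <- data.frame(participant = ids,
                               group = ifelse(ids %in% control_ids,
                                              "control", "patient"))
    fields <- NULL
  }
  parts <- vapply(trials, function(tr) tr$participant, "")
  groups <- participants$group[match(unique(parts), participants$participant)]
  is_ctrl <- unique(parts) %in% control_ids
  utils::write.csv(participants, file.path(config$out_dir, "participants.csv"),
                   row.names = FALSE)

  if ("features" %in% config$analyses) {
    feat <- features_by_participant(trials)
    utils::write.csv(feat, file.path(config$out_dir, "features.csv"),
                     row.names = FALSE)
    fc <- feat[is_ctrl, ]; fp <- feat[!is_ctrl, ]
    if (nrow(fc) >= 2 && nrow(fp) >= 2) {
      cmp <- lapply(c("fix_duration_ms", "sacc_amplitude_deg", "sacc_velocity_dps"),
                    function(v) {
                      g <- compare_groups(fc[[v]], fp[[v]], n_comparisons = 4)
                      list(feature = v, median_control = g$median_a,
                           median_patient = g$median_b, z = g$z, p = g$p,
                           corrected_alpha = g$corrected_alpha,
                           significant = g$significant)
                    })
      summary$features <- cmp
    }
  }

  if ("directions" %in% config$analyses) {
    profs <- lapply(unique(parts), function(id)
      directional_profile(do.call(rbind, lapply(trials[parts == id],
                                                function(tr) tr$saccades))))
    names(profs) <- unique(parts)
    ctrl_profs <- profs[is_ctrl]
    for (id in unique(parts)[!is_ctrl]) {
      rp <- normalized_rank_profile(profs[[id]], ctrl_profs)
      write_rank_profile(rp, file.path(config$out_dir,
                                       sprintf("rank_profile_%s.csv", id)))
    }
  }

  vp_sum <- NULL
  vprec <- NULL
  if ("vp" %in% config$analyses) {
    vpp <- config$vp
    vpp$seed <- config$seed
    vprec <- vp_cohort(trials, control_ids, vpp)
    utils::write.csv(vprec[, c("participant", "clip", "onset", "vp")],
                     file.path(config$out_dir, "vp_records.csv"),
                     row.names = FALSE)
    sev <- if (!is.null(fields))
      participants[participants$group == "patient",
                   c("participant", "md_tested", "ivf_score", "md_diff")]
    else NULL
    vp_sum <- summarize_vp(vprec, sev)
    ctrl_vp <- vp_sum$overall$mean_vp[vp_sum$overall$participant %in% control_ids]
    pat_vp <- vp_sum$overall$mean_vp[!vp_sum$overall$participant %in% control_ids]
    if (length(ctrl_vp) >= 2 && length(pat_vp) >= 2) {
      g <- compare_groups(ctrl_vp, pat_vp, n_comparisons = 4)
      summary$vp <- list(median_control = g$median_a, median_patient = g$median_b,
                         z = g$z, p = g$p, corrected_alpha = g$corrected_alpha,
                         significant = g$significant)
    }
    if (!is.null(vp_sum$correlations))
      summary$vp_correlations <- vp_sum$correlations
  }

  if ("maps" %in% config$analyses) {
    fmaps <- cohort_fixation_maps(trials, control_ids)
    # per-participant pooled map + rank map against controls
    pooled <- lapply(unique(parts), function(id) {
      vecs <- do.call(rbind, lapply(trials[parts == id],
                                    function(tr) to_vf_vectors(tr$fixations)))
      count_map(vecs, fmaps$spec, normalize = "max")
    })
    names(pooled) <- unique(parts)
    ctrl_pool <- pooled[is_ctrl]
    for (id in unique(parts)) {
      write_map(pooled[[id]], file.path(config$out_dir,
                                        sprintf("fixmap_%s.tsv", id)))
      others <- ctrl_pool[names(ctrl_pool) != id]
      if (length(others) >= 2)
        write_map(relative_rank_map(pooled[[id]], others),
                  file.path(config$out_dir, sprintf("rankmap_%s.tsv", id)))
    }
    summary$map_grid <- list(half_x = fmaps$spec$half_x,
                             half_y = fmaps$spec$half_y,
                             bins = c(fmaps$spec$ny, fmaps$spec$nx))
    if (!is.null(fields)) {
      rr <- vapply(names(fields), function(id) {
        vecs <- do.call(rbind, lapply(trials[parts == id],
                                      function(tr) to_vf_vectors(tr$fixations)))
        binned_map_vs_sensitivity(vecs, fields[[id]]$effective)$r
      }, 0)
      utils::write.csv(data.frame(participant = names(fields), r = rr),
                       file.path(config$out_dir, "fixfreq_sensitivity_r.csv"),
                       row.names = FALSE)
      summary$fixfreq_sensitivity_mean_r <- mean(rr, na.rm = TRUE)
    }
  }

  if ("classify" %in% config$analyses) {
    fmaps <- cohort_fixation_maps(trials, control_ids)
    K <- kernel_matrix(fmaps$maps, kernel_spec("all_clips", bandwidth = 2))
    emb <- kpca_project(K)
    proj <- emb$projections
    lab <- ifelse(rownames(proj) %in% control_ids, "control", "patient")
    utils::write.csv(data.frame(participant = rownames(proj), group = lab,
                                proj[, seq_len(min(5, ncol(proj))), drop = FALSE]),
                     file.path(config$out_dir, "embedding.csv"),
                     row.names = FALSE)
    nb <- nb_crossval(proj, lab, classifier_config(seed = config$seed))
    utils::write.csv(data.frame(fold = seq_along(nb$fold_accuracy),
                                accuracy = nb$fold_accuracy),
                     file.path(config$out_dir, "nb_accuracy.csv"),
                     row.names = FALSE)
    summary$classification <- list(mean_accuracy = nb$mean_accuracy,
                                   min_accuracy = nb$min_accuracy,
                                   max_accuracy = nb$max_accuracy,
                                   explained_first2 = sum(emb$explained[1:min(2, length(emb$explained))]))
  }

  if ("ivf" %in% config$analyses && !is.null(fields)) {
    ivf <- do.call(rbind, lapply(names(fields), function(id)
      data.frame(participant = id,
                 md_tested = attr(fields[[id]]$tested, "md"),
                 md_covered = attr(fields[[id]]$covered, "md"),
                 md_diff = attr(fields[[id]]$tested, "md") -
                   attr(fields[[id]]$covered, "md"),
                 ivf_score = ivf_score(fields[[id]]$ivf))))
    utils::write.csv(ivf, file.path(config$out_dir, "ivf_scores.csv"),
                     row.names = FALSE)
    summary$ivf <- list(mean_score = mean(ivf$ivf_score),
                        max_score = max(ivf$ivf_score))
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
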