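with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Viewing-priority parameters
#'
#' Controls for the viewing-priority (VP) statistic: the temporal window that
#' defines "the same moment" of a clip, and the fuzzy c-means clustering that
#' summarizes where the reference cohort is looking at that moment.
#'
#' @param window_ms half-width in ms of the time window around a fixation's
#'   onset (default 500).
#' @param n_clusters clusters fitted to each of the reference and random
#'   sets (default 5; reduced automatically for small sets).
#' @param m fuzzifier, > 1 (default 2).
#' @param tol convergence tolerance on memberships (default 1e-4).
#' @param max_iter maximum fuzzy c-means iterations (default 300).
#' @param seed RNG seed for cluster initialization.
#' @param random_max random-set subsample cap per window (default 300); the
#'   random set is typically much larger than the reference set and is
#'   subsampled (seeded) for speed.
#' @return An object of class `vp_params`.
#' @export
vp_params <- function(window_ms = 500, n_clusters = 5, m = 2, tol = 1e-4,
                      max_iter = 300, seed = 1L, random_max = 300L) {
  stopifnot(n_clusters >= 1, m > 1, window_ms > 0)
  structure(list(window_ms = window_ms, n_clusters = n_clusters, m = m,
                 tol = tol, max_iter = max_iter, seed = as.integer(seed),
                 random_max = as.integer(random_max)),
            class = "vp_params")
}

# membership of points X (n x 2) to centers (K x 2), standard FCM formula
fcm_membership <- function(X, centers, m) {
  n <- nrow(X); K <- nrow(centers)
  if (K == 1) return(matrix(1, n, 1))
  d2 <- rowSums(X^2) - 2 * tcrossprod(X, centers) +
    matrix(rowSums(centers^2), n, K, byrow = TRUE)
  d2[d2 < 0] <- 0
  w <- if (m == 2) 1 / d2 else d2^(-1 / (m - 1))
  U <- w / rowSums(w)
  if (any(d2 < 1e-24)) {
    zero <- d2 < 1e-24
    hit <- rowSums(zero) > 0
    U[hit, ] <- 0
    U[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  U
}

# fuzzy c-means on 2-D points; deterministic given seed.
fcm_fit <- function(X, C, m = 2, tol = 1e-4, max_iter = 300, seed = 1L) {
  X <- as.matrix(X)
  uniq <- unique(X)
  C <- max(1L, min(C, nrow(uniq)))
  if (C == 1) return(list(centers = matrix(colMeans(X), 1), C = 1, converged = TRUE))
  centers <- with_seed(seed, uniq[sample.int(nrow(uniq), C), , drop = FALSE])
  U_old <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U <- fcm_membership(X, centers, m)
    Um <- if (m == 2) U * U else U^m
    centers <- t(Um) %*% X / colSums(Um)
    if (!is.null(U_old) && max(abs(U - U_old)) < tol) { converged <- TRUE; break }
    U_old <- U
  }
  if (!converged)
    warning("fuzzy c-means did not converge within ", max_iter,
            " iterations; using best iterate")
  list(centers = centers, C = C, converged = converged)
}

#' Assemble reference and random fixation sets for one fixation
#'
#' Reference fixations are fixations made by the cohort's other observers on
#' the same clip whose interval overlaps the time window around the scored
#' fixation's onset; random fixations are the cohort's fixations in the same
#' window on the other clips. The scored observer's own fixations are always
#' excluded from both sets.
#'
#' @param fixation one-row data.frame (or list) with `onset` (ms).
#' @param cohort_trials list of [event_trial()] forming the reference cohort.
#' @param clip the clip the scored fixation belongs to.
#' @param exclude_participant id of the scored observer.
#' @param params a [vp_params()].
#' @return list with `reference` and `random` data.frames (`x`, `y`, deg).
#' @export
assemble_sets <- function(fixation, cohort_trials, clip, exclude_participant,
                          params = vp_params()) {
  lo <- fixation$onset - params$window_ms
  hi <- fixation$onset + params$window_ms
  ref <- list(); rnd <- list()
  for (tr in cohort_trials) {
    if (tr$participant == exclude_participant) next
    f <- tr$fixations
    keep <- f$offset >= lo & f$onset <= hi
    if (!any(keep)) next
    part <- f[keep, c("x", "y"), drop = FALSE]
    if (tr$clip == clip) ref[[length(ref) + 1]] <- part
    else rnd[[length(rnd) + 1]] <- part
  }
  list(reference = if (length(ref)) do.call(rbind, ref) else data.frame(x = numeric(), y = numeric()),
       random = if (length(rnd)) do.call(rbind, rnd) else data.frame(x = numeric(), y = numeric()))
}

# Fit the VP model: cluster reference and random sets, pool the centers, and
# assign each center a priority = reference mass / (reference + balanced
# random mass) under that center.
fit_vp_model <- function(reference, random, params = vp_params()) {
  R <- as.matrix(reference)
  n_ref <- nrow(R)
  if (!n_ref) return(NULL)
  fr <- fcm_fit(R, params$n_clusters, params$m, params$tol, params$max_iter,
                params$seed)
  Q <- as.matrix(random)
  n_rand <- nrow(Q)
  if (n_rand > params$random_max) {
    idx <- with_seed(params$seed + 1L, sample.int(n_rand, params$random_max))
    Q <- Q[idx, , drop = FALSE]
    n_rand <- nrow(Q)
  }
  if (n_rand) {
    fq <- fcm_fit(Q, params$n_clusters, params$m, params$tol, params$max_iter,
                  params$seed)
    centers <- rbind(fr$centers, fq$centers)
  } else {
    centers <- fr$centers
  }
  U_ref <- fcm_membership(R, centers, params$m)
  A <- colSums(U_ref)
  if (n_rand) {
    U_rand <- fcm_membership(Q, centers, params$m)
    B <- colSums(U_rand) * (n_ref / n_rand)
  } else {
    # uniform baseline: spread one reference-set's worth of mass evenly
    B <- rep(n_ref / nrow(centers), nrow(centers))
  }
  list(centers = centers, priority = A / (A + B), m = params$m,
       n_reference = n_ref, n_random = n_rand,
       ref_mass = A, rand_mass = B)
}

# Score positions (n x 2 matrix/data.frame) under a fitted VP model.
score_vp <- function(model, positions) {
  P <- as.matrix(positions)
  U <- fcm_membership(P, model$centers, model$m)
  pmin(pmax(drop(U %*% model$priority), 0), 1)
}

#' Viewing priority of a single fixation
#'
#' Fits fuzzy c-means clusters to the reference set and to the random set,
#' assigns each cluster a priority weight — the share of reference mass under
#' it, with the random mass rebalanced to the reference set's size — and
#' scores the fixation as its membership-weighted priority. The result is in
#' \[0, 1\]: 1 when the fixation sits in a purely reference-occupied
#' neighborhood, 0 in a purely random-occupied one, and about 0.5 when
#' reference and random sets are exchangeable.
#'
#' @param position length-2 numeric (deg) or one-row data.frame with `x`,`y`.
#' @param reference,random data.frames with `x`, `y` (deg), as from
#'   [assemble_sets()].
#' @param params a [vp_params()].
#' @return list of class `vp_record`: `vp` (NA when the reference set is
#'   empty), `n_reference`, `n_random`.
#' @export
compute_vp <- function(position, reference, random, params = vp_params()) {
  if (is.data.frame(position)) position <- c(position$x[1], position$y[1])
  model <- fit_vp_model(reference, random, params)
  if (is.null(model)) {
    message("empty reference set: VP undefined for this fixation")
    return(structure(list(vp = NA_real_, n_reference = 0L,
                          n_random = nrow(random)), class = "vp_record"))
  }
  vp <- score_vp(model, matrix(position, 1))
  structure(list(vp = vp, n_reference = model$n_reference,
                 n_random = model$n_random), class = "vp_record")
}

#' Viewing priority for a whole cohort
#'
#' Batch computation of per-fixation VP for every trial, always scoring
#' against the control cohort (also for the controls themselves, leave-one-out).
#' For speed, fixations are grouped into time windows on a `window_ms` grid:
#' the cluster centers of a window are fitted once on the full control
#' cohort, and the leave-one-out exclusion of a scored control is applied
#' exactly to the reference/random mass counts by subtracting that observer's
#' own membership mass before the priorities are formed.
#'
#' @param trials list of [event_trial()] (controls and patients).
#' @param control_ids participant ids forming the reference cohort.
#' @param params a [vp_params()].
#' @return data.frame: `participant`, `clip`, `onset`, `vp`, `n_reference`,
#'   `n_random`.
#' @export
vp_cohort <- function(trials, control_ids, params = vp_params()) {
  parts <- vapply(trials, function(tr) tr$participant, "")
  clips <- vapply(trials, function(tr) tr$clip, "")
  all_clips <- unique(clips)
  # flat control fixation table
  ctrl <- do.call(rbind, lapply(trials[parts %in% control_ids], function(tr)
    cbind(tr$fixations[, c("onset", "offset", "x", "y")],
          participant = tr$participant, clip = tr$clip)))
  out <- vector("list", length(trials))
  stride <- params$window_ms
  for (ci in seq_along(all_clips)) {
    cl <- all_clips[ci]
    same <- ctrl[ctrl$clip == cl, , drop = FALSE]
    other <- ctrl[ctrl$clip != cl, , drop = FALSE]
    idx_tr <- which(clips == cl)
    # window index per scored fixation
    fwin <- lapply(idx_tr, function(i) floor(trials[[i]]$fixations$onset / stride))
    wins <- sort(unique(unlist(fwin)))
    models <- lapply(wins, function(k) {
      c0 <- (k + 0.5) * stride
      lo <- c0 - params$window_ms; hi <- c0 + params$window_ms
      ref <- same[same$offset >= lo & same$onset <= hi, , drop = FALSE]
      if (!nrow(ref)) return(NULL)
      rnd <- other[other$offset >= lo & other$onset <= hi, , drop = FALSE]
      if (nrow(rnd) > params$random_max) {
        ri <- with_seed(params$seed + k, sample.int(nrow(rnd), params$random_max))
        rnd <- rnd[ri, , drop = FALSE]
      }
      fr <- fcm_fit(as.matrix(ref[, c("x", "y")]), params$n_clusters, params$m,
                    params$tol, params$max_iter, params$seed)
      centers <- fr$centers
      if (nrow(rnd)) {
        fq <- fcm_fit(as.matrix(rnd[, c("x", "y")]), params$n_clusters, params$m,
                      params$tol, params$max_iter, params$seed)
        centers <- rbind(centers, fq$centers)
      }
      U_ref <- fcm_membership(as.matrix(ref[, c("x", "y")]), centers, params$m)
      U_rnd <- if (nrow(rnd))
        fcm_membership(as.matrix(rnd[, c("x", "y")]), centers, params$m)
      else matrix(0, 0, nrow(centers))
      list(centers = centers,
           A = colSums(U_ref), B = colSums(U_rnd),
           ref_by = rowsum(U_ref, ref$participant),
           rnd_by = if (nrow(rnd)) rowsum(U_rnd, rnd$participant) else NULL,
           n_ref = nrow(ref), n_rnd = nrow(rnd),
           nref_by = table(ref$participant),
           nrnd_by = if (nrow(rnd)) table(rnd$participant) else NULL)
    })
    names(models) <- as.character(wins)
    # flatten every scored fixation on this clip for batch scoring
    flat <- do.call(rbind, lapply(seq_along(idx_tr), function(j) {
      f <- trials[[idx_tr[j]]]$fixations
      data.frame(j = j, row = seq_len(nrow(f)), x = f$x, y = f$y,
                 win = fwin[[j]],
                 participant = trials[[idx_tr[j]]]$participant,
                 stringsAsFactors = FALSE)
    }))
    res_vp <- rep(NA_real_, nrow(flat))
    res_nref <- integer(nrow(flat)); res_nrnd <- integer(nrow(flat))
    for (k in wins) {
      mod <- models[[as.character(k)]]
      if (is.null(mod)) next
      rows <- which(flat$win == k)
      U_f <- fcm_membership(cbind(flat$x[rows], flat$y[rows]), mod$centers,
                            params$m)
      for (pid in unique(flat$participant[rows])) {
        prow <- rows[flat$participant[rows] == pid]
        A <- mod$A; B <- mod$B
        n_ref <- mod$n_ref; n_rnd <- mod$n_rnd
        if (pid %in% control_ids) {
          if (pid %in% rownames(mod$ref_by)) {
            A <- A - mod$ref_by[pid, ]
            n_ref <- n_ref - as.integer(mod$nref_by[[pid]])
          }
          if (!is.null(mod$rnd_by) && pid %in% rownames(mod$rnd_by)) {
            B <- B - mod$rnd_by[pid, ]
            n_rnd <- n_rnd - as.integer(mod$nrnd_by[[pid]])
          }
        }
        if (n_ref <= 0) next
        Bb <- if (n_rnd > 0) B * (n_ref / n_rnd)
        else rep(n_ref / nrow(mod$centers), nrow(mod$centers))
        pri <- A / (A + Bb)
        res_vp[prow] <- pmin(pmax(
          drop(U_f[match(prow, rows), , drop = FALSE] %*% pri), 0), 1)
        res_nref[prow] <- n_ref; res_nrnd[prow] <- n_rnd
      }
    }
    for (j in seq_along(idx_tr)) {
      tr <- trials[[idx_tr[j]]]
      sel <- flat$j == j
      ord <- order(flat$row[sel])
      out[[idx_tr[j]]] <- data.frame(participant = tr$participant,
                                     clip = tr$clip,
                                     onset = tr$fixations$onset,
                                     vp = res_vp[sel][ord],
                                     n_reference = res_nref[sel][ord],
                                     n_random = res_nrnd[sel][ord])
    }
  }
  do.call(rbind, out)
}

#' Summarize viewing priority per participant
#'
#' Per-trial and overall mean VP per participant (undefined records
#' excluded), plus Pearson correlations of the overall mean VP against
#' supplied severity covariates.
#'
#' @param vp_records data.frame from [vp_cohort()] (or rows of per-fixation
#'   records): `participant`, `clip`, `vp`.
#' @param severity optional data.frame keyed by `participant` with any of
#'   `md_tested`, `ivf_score`, `md_diff`.
#' @return list with `per_trial` (participant, clip, mean_vp, n), `overall`
#'   (participant, mean_vp, n) and `correlations` (covariate, r, n).
#' @export
summarize_vp <- function(vp_records, severity = NULL) {
  ok <- vp_records[!is.na(vp_records$vp), , drop = FALSE]
  per_trial <- stats::aggregate(vp ~ participant + clip, ok, mean)
  names(per_trial)[3] <- "mean_vp"
  nt <- stats::aggregate(vp ~ participant + clip, ok, length)
  per_trial$n <- nt$vp
  overall <- stats::aggregate(mean_vp ~ participant, per_trial, mean)
  overall$n <- stats::aggregate(n ~ participant, per_trial, sum)$n
  correlations <- NULL
  if (!is.null(severity)) {
    mg <- merge(overall, severity, by = "participant")
    covs <- intersect(c("md_tested", "ivf_score", "md_diff"), names(severity))
    correlations <- do.call(rbind, lapply(covs, function(v) {
      ok2 <- is.finite(mg$mean_vp) & is.finite(mg[[v]])
      r <- if (sum(ok2) >= 3) suppressWarnings(pearson_r(mg$mean_vp[ok2], mg[[v]][ok2]))
      else NA_real_
      data.frame(covariate = v, r = r, n = sum(ok2))
    }))
  }
  list(per_trial = per_trial, overall = overall, correlations = correlations)
}
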