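flat_map <- function(m) {
  v <- as.numeric(m$values)
  v[is.na(v)] <- 0
  v
}

map_distance <- function(a, b) sqrt(sum((flat_map(a) - flat_map(b))^2))

#' Kernel specification
#'
#' @param form `"all_clips"` (one kernel over every clip's maps:
#'   \eqn{k_{ij} = \exp(-0.5 ((meanDist_{ij}+maxDist_{ij})/\sigma)^2)}) or
#'   `"per_clip"` (one kernel per clip: \eqn{k_{ij} = \exp(-Dist_{ij})}).
#' @param bandwidth \eqn{\sigma} for the all-clips form, in map-distance
#'   units: 2 for fixation and VP maps, 0.2 for saccade maps (whose values
#'   have much smaller variance).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(form = c("all_clips", "per_clip"), bandwidth = 2) {
  form <- match.arg(form)
  stopifnot(bandwidth > 0)
  structure(list(form = form, bandwidth = bandwidth), class = "kernel_spec")
}

#' Kernel matrix between participants' visual-field maps
#'
#' For the all-clips form, the Euclidean distances between participant i's
#' and participant j's maps of the same clip are summarized by their mean
#' (`meanDist`) and maximum (`maxDist`) and combined into a Gaussian kernel;
#' the diagonal is computed with zero self-distance (so it is exactly 1).
#' For the per-clip form, each clip yields its own kernel
#' \eqn{k_{ij} = e^{-Dist_{ij}}} on the single-clip map distances.
#'
#' @param maps named list (one element per participant) of lists of
#'   [vf_map()] keyed by clip (all participants share the clips and the
#'   grid). A participant with a single map per clip may pass the map
#'   directly for the per-clip form.
#' @param spec a [kernel_spec()].
#' @return For `all_clips`: a symmetric matrix with participant dimnames.
#'   For `per_clip`: a named list of such matrices, one per clip.
#' @export
kernel_matrix <- function(maps, spec = kernel_spec()) {
  ids <- names(maps)
  if (length(ids) < 2) stop("need at least 2 participants")
  clips <- names(maps[[1]])
  flat <- lapply(maps, function(pm) lapply(pm, flat_map))
  dist_clip <- function(clip) {
    X <- do.call(rbind, lapply(flat, `[[`, clip))
    as.matrix(stats::dist(X))
  }
  dists <- lapply(clips, dist_clip)
  if (spec$form == "per_clip") {
    out <- lapply(dists, function(D) {
      K <- exp(-D)
      dimnames(K) <- list(ids, ids)
      K
    })
    names(out) <- clips
    return(out)
  }
  arr <- simplify2array(dists)  # n x n x n_clips
  meanD <- apply(arr, c(1, 2), mean)
  maxD <- apply(arr, c(1, 2), max)
  K <- exp(-0.5 * ((meanD + maxD) / spec$bandwidth)^2)
  diag(K) <- 1
  dimnames(K) <- list(ids, ids)
  K
}

#' Kernel PCA projection
#'
#' Double-centers the kernel matrix, eigendecomposes it, and projects the
#' participants onto the leading components. The printed kernels are not
#' guaranteed positive semidefinite, so negative eigenvalues are dropped and
#' their mass reported. Projections follow the standard kernel-PCA scaling
#' (component k = eigenvector k times the square root of its eigenvalue);
#' each component's sign is fixed by making its largest-magnitude loading
#' positive. Explained-variance fractions are over the retained positive
#' eigenvalues.
#'
#' @param K symmetric kernel matrix.
#' @param tol eigenvalues below `tol * max(eigenvalue)` are dropped.
#' @return list of class `embedding_result`: `projections` (participants x
#'   components), `eigenvalues`, `explained`, `dropped_mass`, `kernel`.
#' @export
kpca_project <- function(K, tol = 1e-10) {
  stopifnot(isSymmetric(unname(K), tol = 1e-8))
  n <- nrow(K)
  H <- diag(n) - matrix(1 / n, n, n)
  Kc <- H %*% K %*% H
  Kc <- (Kc + t(Kc)) / 2
  e <- eigen(Kc, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values), 1e-300)
  if (!any(pos)) {
    warning("kernel has no positive eigenvalues after centering (all maps identical?)")
    return(structure(list(projections = matrix(0, n, 0), eigenvalues = numeric(),
                          explained = numeric(), dropped_mass = sum(abs(e$values)),
                          kernel = K), class = "embedding_result"))
  }
  lam <- e$values[pos]
  V <- e$vectors[, pos, drop = FALSE]
  proj <- V %*% diag(sqrt(lam), length(lam))
  # sign convention: largest-|loading| positive per component
  for (k in seq_len(ncol(proj))) {
    i <- which.max(abs(proj[, k]))
    if (proj[i, k] < 0) proj[, k] <- -proj[, k]
  }
  rownames(proj) <- rownames(K)
  neg_mass <- sum(abs(e$values[e$values < 0]))
  structure(list(projections = proj, eigenvalues = lam,
                 explained = lam / sum(lam), dropped_mass = neg_mass,
                 kernel = K),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("kernel PCA: %d participants, %d components; first two explain %.1f%%; dropped negative mass %.3g\n",
              nrow(x$projections), length(x$eigenvalues),
              100 * sum(x$explained[seq_len(min(2, length(x$explained)))]),
              x$dropped_mass))
  invisible(x)
}

#' Classifier configuration
#'
#' @param n_components projected dimensions used as classifier input
#'   (default 5).
#' @param n_folds cross-validation folds (default 10), stratified by group.
#' @param seed fold-assignment seed.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(n_components = 5, n_folds = 10, seed = 1L) {
  stopifnot(n_components >= 1, n_folds >= 2)
  structure(list(n_components = n_components, n_folds = n_folds,
                 seed = as.integer(seed)), class = "classifier_config")
}

stratified_folds <- function(labels, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (g in unique(labels)) {
      idx <- which(labels == g)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    fold
  })
}

#' Cross-validated naive-Bayes classification of the kPCA embedding
#'
#' Gaussian naive Bayes (one normal likelihood per projected dimension) on
#' the first `n_components` kernel-PCA components, evaluated with stratified
#' k-fold cross-validation. Folds whose training set lacks a class are
#' redrawn with a new seed (reported). Accuracy is reported in the
#' "mean% (min - max%)" convention.
#'
#' @param projections matrix from [kpca_project()] (rows = participants).
#' @param labels factor/character group labels per row.
#' @param config a [classifier_config()].
#' @return list: `fold_accuracy`, `mean_accuracy`, `min_accuracy`,
#'   `max_accuracy`, `formatted`.
#' @export
nb_crossval <- function(projections, labels, config = classifier_config()) {
  labels <- factor(labels)
  d <- min(config$n_components, ncol(projections))
  X <- as.data.frame(projections[, seq_len(d), drop = FALSE])
  names(X) <- paste0("c", seq_len(d))
  seed <- config$seed
  for (attempt in 1:20) {
    fold <- stratified_folds(labels, config$n_folds, seed)
    ks <- sort(unique(fold))  # folds can be empty when participants < folds
    ok <- all(vapply(ks, function(k)
      length(unique(labels[fold != k])) == nlevels(labels), TRUE))
    if (ok) break
    message("refolding with a new seed: a fold had single-class training data")
    seed <- seed + 1L
  }
  acc <- vapply(ks, function(k) {
    tr <- fold != k
    fit <- e1071::naiveBayes(X[tr, , drop = FALSE], labels[tr])
    pred <- stats::predict(fit, X[!tr, , drop = FALSE])
    mean(pred == labels[!tr])
  }, 0)
  list(fold_accuracy = acc, mean_accuracy = mean(acc),
       min_accuracy = min(acc), max_accuracy = max(acc),
       formatted = sprintf("%.1f%% (%.1f - %.1f%%)", 100 * mean(acc),
                           100 * min(acc), 100 * max(acc)))
}
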