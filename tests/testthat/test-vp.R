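# independent closed-form oracle for C = 1: one reference center (the mean),
# one random center; memberships via the fuzzifier-m distance-ratio formula.
oracle_vp_c1 <- function(pos, ref, rnd, m = 2) {
  cr <- colMeans(ref); cq <- colMeans(rnd)
  memb <- function(p) {
    d2 <- c(sum((p - cr)^2), sum((p - cq)^2))
    if (any(d2 < 1e-24)) return(as.numeric(d2 < 1e-24) / sum(d2 < 1e-24))
    w <- d2^(-1 / (m - 1))
    w / sum(w)
  }
  A <- rowSums(vapply(seq_len(nrow(ref)), function(i) memb(as.numeric(ref[i, ])),
                      numeric(2)))
  B <- rowSums(vapply(seq_len(nrow(rnd)), function(i) memb(as.numeric(rnd[i, ])),
                      numeric(2))) * (nrow(ref) / nrow(rnd))
  pri <- A / (A + B)
  sum(memb(pos) * pri)
}

test_that("VP equals the hand-evaluated formula for C = 1 on fixed points", {
  ref <- data.frame(x = c(-1, 0, 1, 0.5, -0.5), y = c(0, 1, 0, -0.5, 0.5))
  rnd <- data.frame(x = c(8, 9, 10, 9.5, 8.5), y = c(8, 9, 10, 8.5, 9.5))
  p <- vp_params(n_clusters = 1)
  for (pos in list(c(0, 0), c(9, 9), c(4.5, 4.5))) {
    rec <- compute_vp(pos, ref, rnd, p)
    expect_equal(rec$vp, oracle_vp_c1(pos, ref, rnd), tolerance = 1e-9,
                 info = paste(pos, collapse = ","))
  }
})

test_that("a fixation inside a tight reference cluster scores near 1", {
  set.seed(3)
  ref <- data.frame(x = rnorm(40, 0, 0.3), y = rnorm(40, 0, 0.3))
  rnd <- data.frame(x = runif(40, 15, 25), y = runif(40, 15, 25))
  rec <- compute_vp(c(0, 0), ref, rnd)
  expect_gte(rec$vp, 0.95)
  # and a fixation in purely random-occupied territory scores near 0
  rec0 <- compute_vp(c(20, 20), ref, rnd)
  expect_lte(rec0$vp, 0.1)
})

test_that("exchangeable reference and random sets give VP near 0.5", {
  vps <- vapply(1:200, function(s) {
    set.seed(s)
    ref <- data.frame(x = rnorm(30, 0, 5), y = rnorm(30, 0, 5))
    rnd <- data.frame(x = rnorm(30, 0, 5), y = rnorm(30, 0, 5))
    pos <- c(rnorm(1, 0, 5), rnorm(1, 0, 5))
    compute_vp(pos, ref, rnd, vp_params(seed = s))$vp
  }, 0)
  expect_lte(abs(mean(vps) - 0.5), 0.1)
})

test_that("VP lies in [0, 1] for every fixation and seed", {
  for (s in 1:20) {
    set.seed(s)
    nr <- sample(3:40, 1)
    ref <- data.frame(x = rnorm(nr, 0, 4), y = rnorm(nr, 0, 4))
    rnd <- data.frame(x = rnorm(nr, 2, 8), y = rnorm(nr, -1, 8))
    v <- compute_vp(c(rnorm(1, 0, 10), rnorm(1, 0, 10)), ref, rnd,
                    vp_params(seed = s))$vp
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("VP is invariant under rigid motions of the whole configuration", {
  set.seed(9)
  ref <- data.frame(x = rnorm(25, 1, 2), y = rnorm(25, -1, 2))
  rnd <- data.frame(x = rnorm(25, 5, 4), y = rnorm(25, 3, 4))
  pos <- c(0.5, -0.5)
  v0 <- compute_vp(pos, ref, rnd)$vp
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(12, -7)
  rot <- function(df) {
    m <- as.matrix(df) %*% t(R)
    data.frame(x = m[, 1] + shift[1], y = m[, 2] + shift[2])
  }
  v1 <- compute_vp(as.numeric(R %*% pos + shift), rot(ref), rot(rnd))$vp
  expect_equal(v0, v1, tolerance = 1e-9)
})

test_that("empty reference gives an undefined VP; empty random falls back", {
  expect_message(
    rec <- compute_vp(c(0, 0), data.frame(x = numeric(), y = numeric()),
                      data.frame(x = 1, y = 1)),
    "empty reference")
  expect_true(is.na(rec$vp))
  set.seed(2)
  ref <- data.frame(x = rnorm(20, 0, 1), y = rnorm(20, 0, 1))
  rec2 <- compute_vp(c(0, 0), ref, data.frame(x = numeric(), y = numeric()))
  expect_gte(rec2$vp, 0.5)
  expect_lte(rec2$vp, 1)
})

test_that("assemble_sets picks window-overlapping cohort fixations, never own", {
  coh <- tiny_cohort(seed = 6, n_controls = 4, n_patients = 0, n_clips = 2,
                     dur = 20)
  trials <- coh$trials
  scored <- trials[[1]]
  fx <- scored$fixations[5, ]
  sets <- assemble_sets(fx, trials, scored$clip, scored$participant)
  lo <- fx$onset - 500; hi <- fx$onset + 500
  # interval-intersection oracle
  exp_ref <- do.call(rbind, lapply(trials, function(tr) {
    if (tr$participant == scored$participant || tr$clip != scored$clip)
      return(NULL)
    f <- tr$fixations
    f[f$offset >= lo & f$onset <= hi, c("x", "y")]
  }))
  expect_equal(nrow(sets$reference), nrow(exp_ref))
  expect_equal(sort(sets$reference$x), sort(exp_ref$x))
  # the scored observer's own fixations appear in neither set
  own <- scored$fixations[scored$fixations$offset >= lo &
                            scored$fixations$onset <= hi, ]
  expect_false(any(own$x %in% sets$reference$x & own$y %in% sets$reference$y))
  # one other observer, same clip only -> empty random set
  two <- trials[vapply(trials, `[[`, "", "clip") == scored$clip][1:2]
  sets2 <- assemble_sets(fx, two, scored$clip, scored$participant)
  expect_gt(nrow(sets2$reference), 0)
  expect_equal(nrow(sets2$random), 0)
})

test_that("the in-package fuzzy c-means agrees with e1071::cmeans", {
  set.seed(17)
  X <- rbind(matrix(rnorm(60, 0, 1), ncol = 2),
             matrix(rnorm(60, 6, 1), ncol = 2))
  fit <- vfgaze:::fcm_fit(X, 2, m = 2, seed = 3)
  ref <- e1071::cmeans(X, centers = fit$centers, m = 2, iter.max = 200)
  o1 <- order(fit$centers[, 1]); o2 <- order(ref$centers[, 1])
  expect_equal(unname(fit$centers[o1, ]), unname(ref$centers[o2, ]),
               tolerance = 1e-3)
})

test_that("batch cohort VP matches per-fixation leave-one-out structure", {
  coh <- tiny_cohort(seed = 8, n_controls = 6, n_patients = 2, n_clips = 2,
                     dur = 15)
  vp <- vp_cohort(coh$trials, coh$control_ids, vp_params(seed = 8))
  expect_true(all(vp$vp >= 0 & vp$vp <= 1, na.rm = TRUE))
  # every trial is scored
  expect_equal(nrow(vp), sum(vapply(coh$trials, function(tr)
    nrow(tr$fixations), 0L)))
  # controls are scored with themselves excluded: reference counts per window
  # must be smaller for a control than for a patient in the same window
  v_ctrl <- vp[vp$participant == coh$control_ids[1], ]
  v_pat <- vp[vp$participant == "P001", ]
  w <- intersect(floor(v_ctrl$onset / 500), floor(v_pat$onset / 500))
  if (length(w)) {
    k <- w[1]
    nc <- v_ctrl$n_reference[floor(v_ctrl$onset / 500) == k][1]
    np <- v_pat$n_reference[floor(v_pat$onset / 500) == k][1]
    expect_lt(nc, np)
  }
})

test_that("summaries average per trial then overall and correlate covariates", {
  rec <- data.frame(participant = rep(c("A", "B", "C"), each = 4),
                    clip = rep(c("c1", "c2"), 6),
                    vp = c(rep(0.7, 4), 0.2, 0.4, 0.2, 0.4, rep(0.5, 4)))
  s <- summarize_vp(rec)
  expect_equal(s$overall$mean_vp[s$overall$participant == "A"], 0.7)
  expect_equal(s$overall$mean_vp[s$overall$participant == "B"], 0.3)
  sev <- data.frame(participant = c("A", "B", "C"), md_tested = c(0.7, 0.3, 0.5))
  s2 <- summarize_vp(rec, sev)
  expect_equal(s2$correlations$r[s2$correlations$covariate == "md_tested"], 1)
})
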