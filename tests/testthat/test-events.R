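test_that("constant gaze yields one fixation spanning the trace and no saccades", {
  tr <- data.frame(t = seq(0, 999, by = 1), x = 0, y = 0)
  ev <- detect_events(tr)
  expect_equal(nrow(ev$fixations), 1)
  expect_equal(ev$fixations$duration, 1000)
  expect_equal(nrow(ev$saccades), 0)
})

test_that("a scripted 5-deg step between holds is detected as one saccade", {
  tr <- scripted_step_trace(c(0, 0), c(5, 0), hold_ms = 400, step_ms = 30)
  ev <- detect_events(tr)
  expect_equal(nrow(ev$fixations), 2)
  expect_equal(nrow(ev$saccades), 1)
  expect_equal(ev$saccades$amplitude, 5, tolerance = 0.01)
  expect_equal(ev$saccades$direction, 0, tolerance = 0.5)
  # peak velocity of the raised cosine: pi/2 * amp / dur = 261.8 deg/s
  expect_gt(ev$saccades$peak_velocity, 200)
  # boundaries within a sample or two of the scripted transition
  expect_equal(ev$saccades$onset, 400, tolerance = 3)
  expect_equal(ev$saccades$offset, 430, tolerance = 3)
})

test_that("events plus gaps exactly tile the sampled span", {
  tr <- scripted_step_trace(c(-3, 2), c(4, -1), hold_ms = 300, step_ms = 40)
  tr$x[200:249] <- NA; tr$y[200:249] <- NA  # a 50-ms gap
  ev <- detect_events(tr)
  total <- sum(ev$fixations$duration) + sum(ev$saccades$duration) +
    sum(ev$gaps$offset - ev$gaps$onset)
  expect_equal(total, nrow(tr) * 1)
})

test_that("degenerate sample input is handled", {
  expect_error(detect_events(data.frame(t = 1:10, x = NA_real_, y = NA_real_)),
               "all gaze samples are NA")
  expect_warning(ev <- detect_events(data.frame(t = 1, x = 0, y = 0)),
                 "fewer than 2")
  expect_equal(nrow(ev$fixations), 0)
})

test_that("detection recovers the simulator's ground-truth events", {
  n_ok <- 0; n_truth <- 0; boundary_err <- 0
  for (s in 1:3) {
    track <- make_track(20, 0.5, seed = s)
    trial <- simulate_trial(track, NULL, observer_model(), seed = s + 10)
    truth <- attr(trial, "truth")
    samples <- samples_from_trial(trial, hz = 1000)
    ev <- detect_events(samples)
    n_truth <- n_truth + nrow(truth$saccades)
    for (i in seq_len(nrow(truth$saccades))) {
      d <- abs(ev$saccades$onset - truth$saccades$onset[i])
      if (length(d) && min(d) <= 25) {
        n_ok <- n_ok + 1
        boundary_err <- max(boundary_err, min(d))
      }
    }
  }
  expect_gte(n_ok / n_truth, 0.95)
})

test_that("visual-field vectors are next-fixation offsets with signed axes", {
  f <- data.frame(x = c(10, 7, 7, 0, 0), y = c(10, 10, 10, 0, -4))
  v <- to_vf_vectors(f)
  expect_equal(v$dx, c(-3, 0, -7, 0))
  expect_equal(v$dy, c(0, 0, -10, -4))
  expect_equal(nrow(to_vf_vectors(f[1, , drop = FALSE])), 0)
})

test_that("basic features pool trials and match a flat recomputation", {
  coh <- tiny_cohort(seed = 2, n_controls = 1, n_patients = 0, n_clips = 3,
                     dur = 15)
  feat <- basic_features(coh$trials)
  all_fd <- unlist(lapply(coh$trials, function(tr) tr$fixations$duration))
  all_sa <- unlist(lapply(coh$trials, function(tr) tr$saccades$amplitude))
  expect_equal(feat$n_fixations, length(all_fd))
  expect_equal(feat$fix_duration_ms, median(all_fd))
  expect_equal(feat$sacc_amplitude_deg, median(all_sa))
  expect_equal(feat$sacc_amplitude_deg_mean, mean(all_sa))
})

test_that("a participant with no saccades gets NA saccade features, not zero", {
  f <- data.frame(onset = 0, offset = 500, duration = 500, x = 0, y = 0)
  s <- data.frame(onset = numeric(), offset = numeric(), duration = numeric(),
                  x0 = numeric(), y0 = numeric(), x1 = numeric(), y1 = numeric(),
                  amplitude = numeric(), direction = numeric(),
                  peak_velocity = numeric())
  feat <- basic_features(list(event_trial("Z", "c", f, s)))
  expect_true(is.na(feat$sacc_amplitude_deg))
  expect_true(is.na(feat$sacc_velocity_dps))
})

test_that("rank-sum p matches exhaustive enumeration for all group sizes <= 6", {
  set.seed(11)
  for (n1 in 2:6) {
    for (n2 in c(2L, 4L, 6L)) {
      a <- round(rnorm(n1), 6); b <- round(rnorm(n2, 0.5), 6)
      g <- compare_groups(a, b)
      expect_equal(g$p, exact_ranksum_p(a, b), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("identical groups are not significant and ties do not crash", {
  g <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_gte(g$p, 0.99)
  expect_false(g$significant)
  g2 <- compare_groups(rep(1, 4), rep(1, 5))
  expect_equal(g2$p, 1)
})

test_that("Bonferroni-corrected alphas are rounded as conventionally reported", {
  expect_equal(compare_groups(1:5, 2:8, n_comparisons = 4)$corrected_alpha, 0.013)
  expect_equal(compare_groups(1:5, 2:8, n_comparisons = 3)$corrected_alpha, 0.017)
})

test_that("pearson_r matches the direct covariance formula and guards degeneracy", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(5)
  a <- rnorm(40); b <- 0.3 * a + rnorm(40)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b), direct, tolerance = 1e-12)
  expect_warning(r0 <- pearson_r(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(r0))
})
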