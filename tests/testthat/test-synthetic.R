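test_that("archetype fields have the intended defect geometry", {
  f0 <- make_field("normal", 0, seed = 1, noise_sd = 0)
  expect_true(all(f0$sensitivity_db == 30))
  expect_equal(attr(f0, "md"), 0)
  blind <- make_field("blind", 1, seed = 1, noise_sd = 0)
  expect_true(all(blind$sensitivity_db == 0))
  expect_equal(ivf_score(merge_ivf(blind, blind)), 104)
  # tunnel with radius 10: every scored location beyond 10 deg scores 2
  tun <- make_field("tunnel", 1, seed = 1, noise_sd = 0, tunnel_radius = 10)
  loc <- hfa_locations("hfa24_2")
  outside <- !loc$blind_spot & sqrt(loc$x_deg^2 + loc$y_deg^2) > 10
  expect_equal(ivf_score(tun), 2 * sum(outside))
  expect_true(all(tun$sensitivity_db[outside] == 0))
  inside <- !loc$blind_spot & sqrt(loc$x_deg^2 + loc$y_deg^2) <= 10
  expect_true(all(tun$sensitivity_db[inside] == 30))
})

test_that("salience tracks are Poisson-jumping, reproducible and in bounds", {
  t0 <- make_track(60, 0, seed = 5)
  expect_equal(nrow(t0$segments), 1)
  expect_identical(make_track(30, 0.5, seed = 9)$segments,
                   make_track(30, 0.5, seed = 9)$segments)
  counts <- vapply(1:500, function(s)
    nrow(make_track(60, 0.5, seed = s)$segments) - 1, 0)
  expect_equal(mean(counts), 30, tolerance = 1.5)
  tr <- make_track(60, 1, seed = 2, spread = c(18, 13))
  expect_true(all(abs(tr$segments$x) <= 18, abs(tr$segments$y) <= 13))
})

test_that("simulated trials tile time and respect the main sequence", {
  tr <- simulate_trial(make_track(30, 0.5, seed = 3), NULL, observer_model(),
                       seed = 4)
  ev <- rbind(tr$fixations[, c("onset", "offset")],
              tr$saccades[, c("onset", "offset")])
  ev <- ev[order(ev$onset), ]
  expect_true(all(abs(ev$onset[-1] - ev$offset[-nrow(ev)]) < 1e-9))
  expect_equal(max(ev$offset), 30000)
  m <- observer_model()
  expect_equal(tr$saccades$peak_velocity,
               m$vmax * (1 - exp(-tr$saccades$amplitude / m$msc)))
  # ground truth log identical to the emitted events
  truth <- attr(tr, "truth")
  expect_identical(truth$fixations, tr$fixations)
  expect_identical(truth$saccades, tr$saccades)
})

test_that("pure center bias keeps mean gaze near the screen center", {
  devs <- vapply(1:20, function(s) {
    tr <- simulate_trial(make_track(60, 0.5, seed = s),
                         NULL, observer_model(p_follow = 0), seed = 100 + s)
    sqrt(mean(tr$fixations$x)^2 + mean(tr$fixations$y)^2)
  }, 0)
  expect_lt(mean(devs), 1)
})

test_that("a blind periphery suppresses long saccades without compensation", {
  tun <- make_field("tunnel", 1, seed = 1, noise_sd = 0, tunnel_radius = 10)
  frac_long <- function(tr) {
    s <- tr$saccades
    vapply(0:17, function(b) {
      in_bin <- s$direction >= 20 * b & s$direction < 20 * (b + 1)
      if (!sum(in_bin)) return(NA_real_)
      mean(s$amplitude[in_bin] > 10)
    }, 0)
  }
  pat <- ctl <- matrix(NA_real_, 20, 18)
  for (s in 1:20) {
    track <- make_track(60, 0.5, seed = s)
    pat[s, ] <- frac_long(simulate_trial(track, tun, observer_model(),
                                         seed = 200 + s))
    ctl[s, ] <- frac_long(simulate_trial(track, NULL, observer_model(),
                                         seed = 400 + s))
  }
  p <- colMeans(pat, na.rm = TRUE); c0 <- colMeans(ctl, na.rm = TRUE)
  expect_true(all(p < c0))
})

test_that("cohorts are deterministic per master seed and respect sizes", {
  c1 <- tiny_cohort(seed = 7, n_controls = 2, n_patients = 2, n_clips = 2,
                    dur = 10)
  c2 <- tiny_cohort(seed = 7, n_controls = 2, n_patients = 2, n_clips = 2,
                    dur = 10)
  expect_identical(c1$trials, c2$trials)
  p1 <- tempfile(); p2 <- tempfile()
  write_event_table(c1$trials, p1); write_event_table(c2$trials, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical emission
  empty <- make_cohort(cohort_config(n_controls = 0, n_patients = 0,
                                     n_clips = 1, clip_duration_s = 5))
  expect_length(empty$trials, 0)
  expect_equal(nrow(c1$participants), 4)
  expect_equal(c1$participants$ivf_score[c1$participants$group == "control"],
               rep(0L, 2))
})

test_that("binocular viewing of asymmetric fields shrinks group differences", {
  amp_diff <- function(regime, s) {
    coh <- make_cohort(cohort_config(
      n_controls = 6, n_patients = 6, archetypes = "tunnel", severity = 1,
      covered_severity = 0.1, regime = regime, n_clips = 3,
      clip_duration_s = 20, seed = s))
    feat <- do.call(rbind, lapply(split(
      seq_along(coh$trials),
      vapply(coh$trials, `[[`, "", "participant")),
      function(ix) basic_features(coh$trials[ix])))
    ctl <- feat$sacc_amplitude_deg[feat$participant %in% coh$control_ids]
    pat <- feat$sacc_amplitude_deg[!feat$participant %in% coh$control_ids]
    median(ctl) - median(pat)
  }
  mono <- vapply(1:8, function(s) amp_diff("monocular", s), 0)
  bino <- vapply(1:8, function(s) amp_diff("binocular", s), 0)
  expect_gt(mean(mono), mean(bino))
  expect_gt(mean(mono), 0)
})
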