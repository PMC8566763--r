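test_that("Gaussian heat map has the closed-form falloff at 1 degree", {
  spec <- map_spec(2.001, 2.001, bin = 0.002, sigma = 1)  # centers hit 0 and 1
  m <- fixation_heatmap(data.frame(dx = 0, dy = 0), spec)
  cx <- bin_centers(spec$x_edges); cy <- rev(bin_centers(spec$y_edges))
  peak <- m$values[which.min(abs(cy)), which.min(abs(cx))]
  off <- m$values[which.min(abs(cy)), which.min(abs(cx - 1))]
  expect_equal(off / peak, exp(-0.5), tolerance = 1e-6)
})

test_that("heat-map mass is conserved away from the edges", {
  set.seed(12)
  spec <- map_spec(20, 20, bin = 2, sigma = 1)
  pts <- data.frame(dx = runif(100, -15, 15), dy = runif(100, -15, 15))
  m <- fixation_heatmap(pts, spec)
  expect_equal(sum(m$values), 100, tolerance = 0.5)
  # empty input gives an all-zero map
  m0 <- fixation_heatmap(data.frame(dx = numeric(), dy = numeric()), spec)
  expect_true(all(m0$values == 0))
})

test_that("heat maps are additive over point sets", {
  set.seed(13)
  spec <- map_spec(10, 8, bin = 2)
  a <- data.frame(dx = rnorm(30), dy = rnorm(30))
  b <- data.frame(dx = rnorm(20, 3), dy = rnorm(20, -2))
  mab <- fixation_heatmap(rbind(a, b), spec)
  expect_equal(mab$values,
               fixation_heatmap(a, spec)$values + fixation_heatmap(b, spec)$values,
               tolerance = 1e-12)
})

test_that("average VP map is the weighted/unweighted heat-map ratio", {
  spec <- map_spec(10, 10, bin = 2)
  pts <- data.frame(dx = c(-2, 2, 0, 1), dy = c(0, 0, 2, -1))
  m <- average_vp_map(pts, rep(0.7, 4), spec)
  expect_true(all(abs(m$values[!m$mask] - 0.7) < 1e-9))
  # far corners have no fixation mass -> masked
  expect_true(m$mask[1, 1])
  # two fixations 4 deg apart with VP 0 and 1: midpoint bin averages to 0.5
  spec2 <- map_spec(6.25, 6.25, bin = 0.5)  # 0 is a bin center
  m2 <- average_vp_map(data.frame(dx = c(-2, 2), dy = 0), c(0, 1), spec2)
  cx <- bin_centers(spec2$x_edges); cy <- rev(bin_centers(spec2$y_edges))
  expect_equal(m2$values[which.min(abs(cy)), which.min(abs(cx))], 0.5,
               tolerance = 1e-6)
})

test_that("count maps match a brute-force counting oracle with half-open bins", {
  set.seed(14)
  spec <- map_spec(7, 5, bin = 2)
  px <- c(runif(300, -8, 8), -7, 0, 6.999)
  py <- c(runif(300, -6, 6), -5, 0, 4.999)
  m <- count_map(data.frame(dx = px, dy = py), spec, normalize = "none")
  expect_equal(m$values, brute_count_map(px, py, spec))
  mm <- count_map(data.frame(dx = px, dy = py), spec, normalize = "max")
  expect_equal(max(mm$values), 1)
  ms <- count_map(data.frame(dx = px, dy = py), spec, normalize = "sum")
  expect_equal(sum(ms$values), 1)
})

test_that("relative rank maps match brute-force counting including ties", {
  set.seed(15)
  spec <- map_spec(6, 4, bin = 2)
  mk <- function() {
    v <- matrix(sample(0:3, spec$ny * spec$nx, replace = TRUE) / 3,
                spec$ny, spec$nx)
    vf_map(v, spec, "proportion")
  }
  pat <- mk(); ctl <- lapply(1:8, function(i) mk())
  rmap <- relative_rank_map(pat, ctl, z_normalize = FALSE)
  for (i in seq_len(spec$ny)) for (j in seq_len(spec$nx)) {
    pool <- vapply(ctl, function(m) m$values[i, j], 0)
    expect_equal(rmap$values[i, j],
                 (sum(pool < pat$values[i, j]) +
                    sum(pool == pat$values[i, j]) / 2) / 8)
  }
  expect_true(all(rmap$values >= 0 & rmap$values <= 1, na.rm = TRUE))
  # patient above all controls -> 1; below all -> 0
  hi <- vf_map(matrix(9, spec$ny, spec$nx), spec, "proportion")
  expect_true(all(relative_rank_map(hi, ctl, z_normalize = FALSE)$values == 1))
  lo <- vf_map(matrix(-9, spec$ny, spec$nx), spec, "proportion")
  expect_true(all(relative_rank_map(lo, ctl, z_normalize = FALSE)$values == 0))
})

test_that("leave-one-out rank maps center near 0.5 for a homogeneous cohort", {
  set.seed(16)
  spec <- map_spec(10, 8, bin = 2)
  maps <- lapply(1:12, function(i)
    count_map(data.frame(dx = rnorm(300, 0, 4), dy = rnorm(300, 0, 3)), spec,
              normalize = "max"))
  means <- vapply(seq_along(maps), function(i) {
    r <- relative_rank_map(maps[[i]], maps[-i])
    mean(r$values[!r$mask])
  }, 0)
  expect_true(all(means >= 0.35 & means <= 0.65))
})

test_that("Crabb saccade maps exclude the central four bins and sum to 1", {
  spec <- map_spec(12, 10, bin = 2, central_exclusion = TRUE)
  expect_equal(spec$nx * spec$ny, 120)
  m <- saccade_map(data.frame(dx = 5, dy = 5), spec)
  expect_equal(sum(m$mask), 4)                      # 116 included bins
  expect_equal(sum(m$values, na.rm = TRUE), 1)
  expect_equal(max(m$values, na.rm = TRUE), 1)      # single endpoint bin
  # an endpoint in the central region is dropped from the saccade map
  m2 <- saccade_map(data.frame(dx = c(0.5, 5), dy = c(0.5, 5)), spec)
  expect_equal(sum(m2$values, na.rm = TRUE), 1)
  expect_equal(max(m2$values, na.rm = TRUE), 1)
  # but kept by the fixation-distribution variant
  m3 <- count_map(data.frame(dx = c(0.5, 5), dy = c(0.5, 5)),
                  map_spec(12, 10, bin = 2), normalize = "sum")
  expect_equal(sum(m3$values), 1)
  expect_equal(max(m3$values), 0.5)
  set.seed(18)
  mr <- saccade_map(data.frame(dx = runif(500, -14, 14),
                               dy = runif(500, -12, 12)), spec)
  expect_equal(sum(mr$values, na.rm = TRUE), 1, tolerance = 1e-12)
})

test_that("perimetry-aligned binning pairs bins with dB and correlates", {
  f <- make_field("normal", 0, seed = 1, noise_sd = 0)
  pts <- data.frame(dx = runif(400, -27, 27), dy = runif(400, -21, 21))
  res <- binned_map_vs_sensitivity(pts, f)
  expect_true(is.na(res$r))  # flat sensitivity -> zero variance, flagged
  # constructed exact linear relation
  f2 <- make_field("tunnel", 1, seed = 1, noise_sd = 0)
  loc <- f2[!f2$blind_spot, ]
  reps <- pmax(1, round(loc$sensitivity_db))
  pts2 <- data.frame(dx = rep(loc$x_deg, reps), dy = rep(loc$y_deg, reps))
  res2 <- binned_map_vs_sensitivity(pts2, f2)
  expect_gt(res2$r, 0.9)
  expect_equal(res2$n_locations, 52)
})

test_that("z-normalization standardizes unmasked bins", {
  spec <- map_spec(6, 6, bin = 2)
  set.seed(19)
  m <- vf_map(matrix(runif(36, 1, 5), 6, 6), spec, "proportion")
  z <- z_normalize_map(m)
  expect_equal(mean(z$values), 0, tolerance = 1e-12)
  expect_equal(sd(as.numeric(z$values)), 1, tolerance = 1e-12)
})
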