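# Independent oracles used across the suite. These deliberately use naive
# enumeration / looping implementations, separate from the package's code
# paths.

# Exact two-sided rank-sum p by exhaustive enumeration of all group
# relabelings (tie-free data).
exact_ranksum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx_a) {
    av <- pooled[idx_a]; bv <- pooled[-idx_a]
    sum(outer(av, bv, ">")) + sum(outer(av, bv, "==")) / 2
  }
  U_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(n1 + n2, n1), 2, u_of)
  pl <- mean(all_u <= U_obs)
  pg <- mean(all_u >= U_obs)
  min(1, 2 * min(pl, pg))
}

# Brute-force bin-count map matching count_map()'s grid conventions.
brute_count_map <- function(px, py, spec) {
  m <- matrix(0, spec$ny, spec$nx)
  for (i in seq_along(px)) {
    for (cx in seq_len(spec$nx)) {
      for (cy in seq_len(spec$ny)) {
        if (px[i] >= spec$x_edges[cx] && px[i] < spec$x_edges[cx + 1] &&
            py[i] >= spec$y_edges[cy] && py[i] < spec$y_edges[cy + 1]) {
          m[spec$ny - cy + 1, cx] <- m[spec$ny - cy + 1, cx] + 1
        }
      }
    }
  }
  m
}

# Direct centered-eigendecomposition kernel-PCA oracle.
oracle_kpca <- function(K) {
  n <- nrow(K)
  one <- matrix(1 / n, n, n)
  Kc <- K - one %*% K - K %*% one + one %*% K %*% one
  e <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(abs(e$values))
  list(values = e$values[keep],
       proj = sweep(e$vectors[, keep, drop = FALSE], 2,
                    sqrt(e$values[keep]), "*"))
}

# A tiny deterministic cohort for unit tests (not the study-sized one).
tiny_cohort <- function(seed = 1, n_controls = 5, n_patients = 3,
                        n_clips = 2, dur = 20, archetypes = "tunnel",
                        severity = 1, regime = "monocular",
                        compensation = 0) {
  make_cohort(cohort_config(
    n_controls = n_controls, n_patients = n_patients, archetypes = archetypes,
    severity = severity, regime = regime, n_clips = n_clips,
    clip_duration_s = dur, compensation = compensation, seed = seed))
}

# Hand-scripted gaze trace: hold at p0, smooth step to p1, hold.
scripted_step_trace <- function(p0 = c(0, 0), p1 = c(5, 0), hold_ms = 400,
                                step_ms = 30, hz = 1000) {
  dt <- 1000 / hz
  t <- seq(0, 2 * hold_ms + step_ms - dt / 2, by = dt)
  x <- numeric(length(t)); y <- numeric(length(t))
  for (i in seq_along(t)) {
    if (t[i] < hold_ms) {
      x[i] <- p0[1]; y[i] <- p0[2]
    } else if (t[i] < hold_ms + step_ms) {
      w <- (1 - cos(pi * (t[i] - hold_ms) / step_ms)) / 2
      x[i] <- p0[1] + w * (p1[1] - p0[1])
      y[i] <- p0[2] + w * (p1[2] - p0[2])
    } else {
      x[i] <- p1[1]; y[i] <- p1[2]
    }
  }
  data.frame(t = t, x = x, y = y)
}

with_seed2 <- function(seed, expr) { set.seed(seed); expr }
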