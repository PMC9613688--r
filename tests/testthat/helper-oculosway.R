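# Shared fixtures and independent oracles, built in code.

# A subject with no stochastic nuisance: deterministic latency, no errors,
# no noise, no intrusions.
quiet_subject <- function(latency_mean = 0.2, latency_sd = 0,
                          error_prob = 0, gaze_noise_sd = 0,
                          intrusion_rate = 0, pupil_noise_sd = 0, ...) {
  subject_model(latency_mean = latency_mean, latency_sd = latency_sd,
                error_prob = error_prob, gaze_noise_sd = gaze_noise_sd,
                intrusion_rate = intrusion_rate,
                pupil_noise_sd = pupil_noise_sd, ...)
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign patterns
# (valid for untied, nonzero differences).
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  stopifnot(n <= 12, !any(duplicated(rk)))
  W_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(W_all <= W_obs), mean(W_all >= W_obs)))
}

# Brute-force convex hull area: an ordered pair (i, j) is a hull edge iff
# every other point lies on or to the left of it; vertices are ordered by
# angle about the centroid and fed to the shoelace formula.
brute_hull_area <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3) return(0)
  on_hull <- rep(FALSE, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    v <- pts[j, ] - pts[i, ]
    s <- (pts[, 1] - pts[i, 1]) * v[2] - (pts[, 2] - pts[i, 2]) * v[1]
    if (all(s <= 1e-12)) on_hull[c(i, j)] <- TRUE
  }
  h <- pts[on_hull, , drop = FALSE]
  ctr <- colMeans(h)
  h <- h[order(atan2(h[, 2] - ctr[2], h[, 1] - ctr[1])), , drop = FALSE]
  x <- h[, 1]; y <- h[, 2]
  k <- c(2:nrow(h), 1)
  abs(sum(x * y[k] - x[k] * y)) / 2
}

# Spearman rho from mid-ranks by the Pearson-on-ranks definition.
spearman_midrank <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Synthetic gaze trace holding a single sigmoidal step (for detector tests).
step_trace <- function(amplitude = 8, peak_speed = 350, sample_rate = 1000,
                       duration = 2, t_move = 1) {
  dt <- 1 / sample_rate
  t <- seq(0, duration, by = dt)
  dur <- (2.2 * abs(amplitude) + 21) / 1000
  # slope constant chosen so the truncated, rescaled logistic really peaks
  # at `peak_speed` (same fixed point the simulator converges to)
  k <- 4 * peak_speed / abs(amplitude)
  for (i in 1:25) {
    s <- plogis(k * dur / 2) - plogis(-k * dur / 2)
    k <- 4 * peak_speed * s / abs(amplitude)
  }
  f <- plogis(k * (pmin(pmax(t - t_move, 0), dur) - dur / 2))
  f0 <- plogis(-k * dur / 2); f1 <- plogis(k * dur / 2)
  prof <- (f - f0) / (f1 - f0)
  prof[t - t_move <= 0] <- 0
  prof[t - t_move >= dur] <- 1
  tibble::new_tibble(
    list(t = t, gaze_h = amplitude * prof, gaze_v = rep(0, length(t)),
         pupil = rep(3.5, length(t)), valid = rep(TRUE, length(t))),
    nrow = length(t), class = "gaze_trace", sample_rate = sample_rate
  )
}

# Null / shifted one-parameter long tables for the factorial battery.
latency_table <- function(n_subjects = 20, seed = 1,
                          env_shift = c("2D" = 0, "3D" = 0,
                                        "VM" = 0, "SO" = 0)) {
  tab <- demo_long_table(n_subjects = n_subjects, seed = seed,
                         environment_shift = env_shift,
                         null = all(env_shift == 0))
  tab[tab$parameter == "latency_mean", ]
}
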