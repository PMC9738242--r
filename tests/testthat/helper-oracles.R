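# Independent oracles and fixture builders shared across the suite.

# O(m^2) pair-enumeration dispersion oracle: population z-scores, samples
# with |z| > 2 on any non-constant axis excluded, mean absolute pairwise
# difference of the remaining z-scores per axis.
dispersion_oracle <- function(seg) {
  seg <- as.matrix(seg)
  m <- nrow(seg)
  mu <- colMeans(seg)
  sdev <- sqrt(colMeans(sweep(seg, 2, mu)^2))
  z <- sweep(sweep(seg, 2, mu), 2, ifelse(sdev > 0, sdev, 1), "/")
  z[, sdev == 0] <- 0
  valid <- rep(TRUE, m)
  for (a in 1:3) if (sdev[a] > 0) valid <- valid & abs(z[, a]) <= 2
  out <- numeric(3)
  v <- which(valid)
  if (length(v) >= 2) {
    S <- choose(length(v), 2)
    for (a in 1:3) {
      if (sdev[a] == 0) next
      zz <- z[v, a]
      out[a] <- sum(abs(outer(zz, zz, "-"))) / 2 / S
    }
  }
  names(out) <- c("disp_ap", "disp_ml", "disp_ver")
  out
}

# exhaustive k-medoid search: minimal total point-to-medoid distance
exhaustive_kmedoid_objective <- function(pts, k) {
  D <- as.matrix(dist(pts))
  subsets <- combn(nrow(pts), k)
  min(apply(subsets, 2, function(ss)
    sum(apply(D[, ss, drop = FALSE], 1, min))))
}

rand_segment <- function(m, scale = 1, outliers = 0) {
  seg <- matrix(rnorm(3 * m, sd = scale), m, 3)
  if (outliers > 0 && m > outliers) {
    idx <- sample.int(m, outliers)
    seg[idx, ] <- seg[idx, ] + sample(c(-1, 1), 1) * 6 * scale
  }
  seg
}

tiny_session <- function(seed = 1, days = 1, day_len_s = 120, fs_hz = 16,
                         profile = subject_profile("HE", subject_sd = 0.2)) {
  generate_subject(profile, days = days, day_len_s = day_len_s,
                   fs_hz = fs_hz, seed = seed, subject_id = "T01")
}

tiny_config <- function(seed = 1, n = 4, days = 1, day_len_s = 120,
                        fs_hz = 16, windows = c(3, 10, 60)) {
  cohort_config(n_he = n, n_pd = n, days = days, day_len_s = day_len_s,
                fs_hz = fs_hz, windows = windows, seed = seed)
}

# Cohort with group structure spread over time scales: rare conspicuous
# rest tremor (3 s scale), bout-to-bout intensity spread (10-60 s) and
# shorter bouts (300-900 s), with matched mean activity.
multiscale_config <- function(seed, n_he = 12, n_pd = 12, days = 2) {
  cohort_config(
    n_he = n_he, n_pd = n_pd, days = days, seed = seed,
    he = subject_profile("HE", bout_mean_s = 120, bout_intensity_sd = 0.2,
                         subject_sd = 0.3),
    pd = subject_profile("PD", tremor_rate = 0.15, tremor_amp_g = 0.25,
                         activity_scale = 1, bout_mean_s = 45,
                         bout_intensity_sd = 0.8, subject_sd = 0.3))
}

# descriptor cloud with `modes` well-separated planted modes in 10-d
planted_mode_descriptors <- function(seed, modes = 4, per_mode = 80) {
  set.seed(seed)
  centers <- matrix(rnorm(modes * 10, sd = 8), modes, 10)
  do.call(rbind, lapply(seq_len(modes), function(i)
    sweep(matrix(rnorm(per_mode * 10, sd = 0.5), per_mode, 10),
          2, centers[i, ], "+")))
}
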