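#' Movement profile of a simulated subject
#'
#' Parameterises the signal generator for one group of subjects.  The
#' generated wrist signal is a fixed per-subject gravity vector plus
#' bout-structured movement (low-pass-filtered Gaussian bursts gated by a
#' two-state active/rest process with exponential bout durations), a
#' rest-tremor sinusoid in the 4--6 Hz band added to a random fraction of
#' rest bouts, and white sensor noise.  Parkinsonian signals differ from
#' healthy ones by a reduced movement amplitude (`activity_scale` < 1),
#' shorter activity bouts, and the presence of rest tremor.
#'
#' Group defaults emulate a mild-to-moderate PD cohort: a 20% reduction in
#' movement amplitude, shorter activity bouts, and low-amplitude
#' (~0.15 g) 5 Hz rest tremor expressed in a minority of rest bouts.
#' Between-subject heterogeneity (`subject_sd`) is deliberately large, as
#' free-living activity levels vary far more between people than between
#' diagnostic groups.
#'
#' @param group `"HE"` (healthy elderly) or `"PD"`.
#' @param tremor_rate probability that a rest bout carries a tremor episode.
#' @param tremor_freq_hz tremor oscillation frequency (Hz).
#' @param tremor_amp_g tremor amplitude (g).
#' @param activity_scale multiplicative movement-intensity factor
#'   (dimensionless; < 1 reproduces the globally reduced movement of PD).
#' @param bout_mean_s mean activity/rest bout duration (s).
#' @param bout_intensity_sd log-scale SD of the mean-one bout-level
#'   intensity multiplier: how much movement vigour varies from bout to
#'   bout.  Group differences here change the distribution of window
#'   descriptors without shifting their within-window means.
#' @param noise_sd_g white sensor-noise standard deviation (g).
#' @param day_effect_sd log-scale SD of the day-to-day activity and tremor
#'   multipliers; > 0 makes single days noisy summaries of a subject, so
#'   that accumulating days genuinely adds information.
#' @param subject_sd log-scale SD of between-subject jitter applied to
#'   `activity_scale` and `tremor_amp_g`.
#' @return A `wb_profile` list.
#' @examples
#' subject_profile("PD", tremor_amp_g = 0.3)
#' @export
subject_profile <- function(group = c("HE", "PD"),
                            tremor_rate = if (group == "PD") 0.4 else 0,
                            tremor_freq_hz = 5,
                            tremor_amp_g = if (group == "PD") 0.15 else 0,
                            activity_scale = if (group == "PD") 0.8 else 1,
                            bout_mean_s = if (group == "PD") 60 else 90,
                            bout_intensity_sd = 0.3,
                            noise_sd_g = 0.02,
                            day_effect_sd = 0.3,
                            subject_sd = 0.35) {
  group <- match.arg(group)
  if (tremor_rate < 0 || tremor_rate > 1)
    wb_stop("tremor_rate must be in [0, 1]", class = "wb_invalid_config")
  if (tremor_amp_g < 0 || noise_sd_g < 0 || day_effect_sd < 0 || subject_sd < 0)
    wb_stop("amplitudes and SDs must be non-negative", class = "wb_invalid_config")
  if (activity_scale < 0)
    wb_stop("activity_scale must be non-negative", class = "wb_invalid_config")
  if (bout_intensity_sd < 0)
    wb_stop("bout_intensity_sd must be non-negative",
            class = "wb_invalid_config")
  if (tremor_freq_hz <= 0 || bout_mean_s <= 0)
    wb_stop("tremor_freq_hz and bout_mean_s must be positive",
            class = "wb_invalid_config")
  structure(list(group = group, tremor_rate = tremor_rate,
                 tremor_freq_hz = tremor_freq_hz, tremor_amp_g = tremor_amp_g,
                 activity_scale = activity_scale, bout_mean_s = bout_mean_s,
                 bout_intensity_sd = bout_intensity_sd,
                 noise_sd_g = noise_sd_g, day_effect_sd = day_effect_sd,
                 subject_sd = subject_sd),
            class = "wb_profile")
}

# Baseline movement-burst SD (g) before activity scaling; the AR(1)
# low-pass coefficient targets an effective bandwidth of ~1.5 Hz.
MOVEMENT_SD_G <- 0.35
MOVEMENT_BW_HZ <- 1.5

# Alternating active/rest bouts with exponential durations (s).
sim_bouts <- function(day_len_s, bout_mean_s) {
  state <- sample(c("active", "rest"), 1)
  starts <- numeric(0); states <- character(0); t <- 0
  while (t < day_len_s) {
    dur <- max(2, rexp(1, 1 / bout_mean_s))
    starts <- c(starts, t); states <- c(states, state)
    t <- t + dur
    state <- if (state == "active") "rest" else "active"
  }
  data.frame(start_s = starts,
             end_s = c(starts[-1], day_len_s),
             state = states, stringsAsFactors = FALSE)
}

#' Generate one subject's tri-axial recording
#'
#' Simulates `days` consecutive day units of wrist acceleration at
#' `fs_hz`.  Each day is generated from its own RNG stream derived from
#' `seed`, so a recording truncated to its first `d` days is identical to
#' one generated with `days = d` and the same seed -- the property the
#' days-of-data analysis relies on.  Samples are clipped to
#' `range_g` (the +/- 8 g span of the emulated device).
#'
#' @param profile a [subject_profile()].
#' @param days number of simulated day units.
#' @param day_len_s duration of one day unit (s).
#' @param fs_hz sampling rate (Hz).
#' @param seed integer seed; identical inputs give bit-identical output.
#' @param subject_id identifier stored in the session.
#' @param range_g sensor clipping limit (g).
#' @return An `accel_session`: list with `subject_id`, `group`, `fs_hz`,
#'   `duration_s`, `samples` (n x 3 matrix, g), `seed`, `bouts` (bout table
#'   with tremor flags) and the generating profile.
#' @examples
#' s <- generate_subject(subject_profile("PD"), days = 1, day_len_s = 60,
#'                       fs_hz = 32, seed = 1)
#' dim(s$samples)
#' @export
generate_subject <- function(profile, days = 7, day_len_s = 1800, fs_hz = 32,
                             seed = 1, subject_id = "S01", range_g = 8) {
  stopifnot(inherits(profile, "wb_profile"))
  if (day_len_s <= 0 || fs_hz <= 0 || days < 1)
    wb_stop("days, day_len_s and fs_hz must be positive",
            class = "wb_invalid_config")
  n_day <- round(day_len_s * fs_hz)
  if (n_day < 1)
    wb_stop("day_len_s x fs_hz must be at least one sample",
            class = "wb_invalid_config")

  # subject-level draws: gravity orientation and between-subject jitter
  subj <- with_seed(derive_seed(seed, 0), {
    theta <- runif(1, 0, 15 * pi / 180)
    phi <- runif(1, 0, 2 * pi)
    list(gravity = c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta)),
         act_mult = rlnorm(1, 0, profile$subject_sd),
         trem_mult = rlnorm(1, 0, profile$subject_sd))
  })

  ar <- exp(-2 * pi * MOVEMENT_BW_HZ / fs_hz)
  ar_sd <- sqrt(1 / (1 - ar^2))
  xyz <- matrix(0, days * n_day, 3)
  bout_all <- vector("list", days)

  for (d in seq_len(days)) {
    day <- with_seed(derive_seed(seed, d), {
      act_day <- profile$activity_scale * subj$act_mult *
        rlnorm(1, 0, profile$day_effect_sd)
      trem_day <- profile$tremor_amp_g * subj$trem_mult *
        rlnorm(1, 0, profile$day_effect_sd)
      bouts <- sim_bouts(day_len_s, profile$bout_mean_s)
      tt <- (seq_len(n_day) - 1) / fs_hz
      # per-sample movement intensity: 0 at rest, a mean-one lognormal
      # bout-level multiplier during activity (bout-to-bout variability)
      intensity <- rep(0, n_day)
      isd <- profile$bout_intensity_sd
      for (b in which(bouts$state == "active"))
        intensity[tt >= bouts$start_s[b] & tt < bouts$end_s[b]] <-
          if (isd > 0) rlnorm(1, -isd^2 / 2, isd) else 1
      m <- matrix(0, n_day, 3)
      if (act_day > 0) {
        for (a in 1:3) {
          burst <- as.numeric(stats::filter(rnorm(n_day), ar,
                                            method = "recursive"))
          m[, a] <- burst / ar_sd * MOVEMENT_SD_G * act_day * intensity
        }
      }
      rest_idx <- which(bouts$state == "rest")
      bouts$tremor <- FALSE
      if (profile$tremor_rate > 0 && trem_day > 0) {
        for (b in rest_idx) {
          if (runif(1) < profile$tremor_rate) {
            bouts$tremor[b] <- TRUE
            sel <- tt >= bouts$start_s[b] & tt < bouts$end_s[b]
            v <- rnorm(3); v <- v / sqrt(sum(v^2))
            amp <- trem_day * rlnorm(1, 0, 0.2)
            wave <- amp * sin(2 * pi * profile$tremor_freq_hz * tt[sel] +
                                runif(1, 0, 2 * pi))
            m[sel, ] <- m[sel, ] + outer(wave, v)
          }
        }
      }
      if (profile$noise_sd_g > 0)
        m <- m + matrix(rnorm(3 * n_day, 0, profile$noise_sd_g), n_day, 3)
      list(m = m, bouts = bouts)
    })
    off <- (d - 1) * n_day
    xyz[off + seq_len(n_day), ] <- day$m
    b <- day$bouts
    b$start_s <- b$start_s + (d - 1) * day_len_s
    b$end_s <- b$end_s + (d - 1) * day_len_s
    b$day <- d
    bout_all[[d]] <- b
  }
  xyz <- sweep(xyz, 2, subj$gravity, "+")
  xyz[xyz > range_g] <- range_g
  xyz[xyz < -range_g] <- -range_g
  colnames(xyz) <- c("x", "y", "z")
  structure(list(subject_id = subject_id, group = profile$group,
                 fs_hz = fs_hz, duration_s = days * day_len_s,
                 samples = xyz, seed = seed,
                 bouts = do.call(rbind, bout_all), profile = profile),
            class = "accel_session")
}

#' @export
print.accel_session <- function(x, ...) {
  cat(sprintf("<accel_session %s (%s): %.0f s at %g Hz, %d samples>\n",
              x$subject_id, x$group, x$duration_s, x$fs_hz, nrow(x$samples)))
  invisible(x)
}

#' Cohort simulation settings
#'
#' Bundles cohort composition, recording geometry and the per-group
#' movement profiles.  The default cohort mirrors the study population
#' (32 healthy elderly, 28 PD) over seven day units.  The `"desk"` preset
#' (default) compresses a day to 1800 s at 32 Hz so that a full cohort is
#' tractable on a desktop; `"paper"` uses 86,400-s days at 100 Hz.  Window
#' lengths are kept in physical seconds under both presets, so per-strategy
#' segment counts shrink by the compression factor while their ratios
#' across strategies are preserved.
#'
#' @param n_he,n_pd group sizes.
#' @param days number of day units (1--7).
#' @param preset `"desk"` or `"paper"`; sets `day_len_s`/`fs_hz` defaults.
#' @param day_len_s,fs_hz override the preset geometry.
#' @param he,pd group [subject_profile()]s.
#' @param windows window lengths in seconds.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return A `wb_cohort_config` list.
#' @examples
#' cohort_config(n_he = 4, n_pd = 4, days = 1)
#' @export
cohort_config <- function(n_he = 32, n_pd = 28, days = 7,
                          preset = c("desk", "paper"),
                          day_len_s = NULL, fs_hz = NULL,
                          he = subject_profile("HE"),
                          pd = subject_profile("PD"),
                          windows = c(3, 10, 60, 300, 900),
                          seed = 1) {
  preset <- match.arg(preset)
  if (is.null(day_len_s)) day_len_s <- if (preset == "desk") 1800 else 86400
  if (is.null(fs_hz)) fs_hz <- if (preset == "desk") 32 else 100
  if (n_he < 0 || n_pd < 0 || days < 1 || days > 7)
    wb_stop("need n_he, n_pd >= 0 and days in 1..7",
            class = "wb_invalid_config")
  if (day_len_s <= 0 || fs_hz <= 0)
    wb_stop("day_len_s and fs_hz must be positive",
            class = "wb_invalid_config")
  stopifnot(inherits(he, "wb_profile"), inherits(pd, "wb_profile"))
  structure(list(n_he = n_he, n_pd = n_pd, days = days, preset = preset,
                 day_len_s = day_len_s, fs_hz = fs_hz, he = he, pd = pd,
                 windows = sort(windows), seed = as.integer(seed)),
            class = "wb_cohort_config")
}

#' Null-effect variant of a cohort configuration
#'
#' Gives the PD group the healthy profile (only the group label differs),
#' producing cohorts with no class signal -- the null condition used to
#' calibrate the classification pipeline around chance accuracy.
#'
#' @param config a [cohort_config()].
#' @return The modified configuration.
#' @export
null_cohort_config <- function(config = cohort_config()) {
  p <- config$he
  p$group <- "PD"
  config$pd <- p
  config
}

per_subject_seeds <- function(config) {
  n <- config$n_he + config$n_pd
  vapply(seq_len(n), function(i) derive_seed(config$seed, 13 + i), integer(1))
}

cohort_roster <- function(config) {
  if (config$n_he + config$n_pd == 0)
    return(data.frame(subject_id = character(0), group = character(0),
                      seed = integer(0)))
  data.frame(
    subject_id = c(sprintf("HE%02d", seq_len(config$n_he)),
                   sprintf("PD%02d", seq_len(config$n_pd))),
    group = rep(c("HE", "PD"), c(config$n_he, config$n_pd)),
    seed = per_subject_seeds(config), stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @param days optionally generate only the first `days` day units
#'   (defaults to `config$days`); because each day has its own RNG stream,
#'   this equals truncating the full recording.
#' @return An `accel_cohort`: list of `accel_session`s plus the config.
#' @examples
#' co <- generate_cohort(cohort_config(n_he = 2, n_pd = 2, days = 1,
#'                                     day_len_s = 60, fs_hz = 16))
#' length(co$sessions)
#' @export
generate_cohort <- function(config, days = NULL) {
  stopifnot(inherits(config, "wb_cohort_config"))
  if (is.null(days)) days <- config$days
  roster <- cohort_roster(config)
  sessions <- lapply(seq_len(nrow(roster)), function(i) {
    prof <- if (roster$group[i] == "HE") config$he else config$pd
    generate_subject(prof, days = days, day_len_s = config$day_len_s,
                     fs_hz = config$fs_hz, seed = roster$seed[i],
                     subject_id = roster$subject_id[i])
  })
  names(sessions) <- roster$subject_id
  structure(list(sessions = sessions, roster = roster, config = config),
            class = "accel_cohort")
}

#' @export
print.accel_cohort <- function(x, ...) {
  cat(sprintf("<accel_cohort: %d HE + %d PD sessions>\n",
              sum(x$roster$group == "HE"), sum(x$roster$group == "PD")))
  invisible(x)
}

#' Read and write session CSV files
#'
#' Sessions are stored as CSV with columns `timestamp, x, y, z` (seconds
#' and g) preceded by `#`-prefixed metadata lines (`subject_id`, `group`,
#' `fs_hz`, `seed`).  Values are written with 9 significant digits.
#' Reading validates that timestamps advance uniformly by `1/fs_hz`; a gap
#' or non-monotonic step raises an error naming the offending line.
#'
#' @param session an `accel_session`.
#' @param path file path.
#' @return `read_session_csv()` returns an `accel_session`;
#'   `write_session_csv()` returns `path` invisibly.
#' @export
write_session_csv <- function(session, path) {
  stopifnot(inherits(session, "accel_session"))
  n <- nrow(session$samples)
  ts <- (seq_len(n) - 1) / session$fs_hz
  hdr <- c(paste0("# subject_id: ", session$subject_id),
           paste0("# group: ", session$group),
           paste0("# fs_hz: ", format(session$fs_hz, digits = 12)),
           paste0("# seed: ", session$seed),
           "timestamp,x,y,z")
  rows <- sprintf("%.6f,%.9g,%.9g,%.9g", ts, session$samples[, 1],
                  session$samples[, 2], session$samples[, 3])
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta_lines <- lines[is_meta]
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:", "", kv))
  }
  body <- lines[!is_meta]
  if (length(body) < 2)
    wb_stop("no data rows in ", path, class = "wb_parse_error")
  fields <- strsplit(body[-1], ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4)) {
    bad <- which(nf != 4)[1]
    wb_stop("malformed row at line ", sum(is_meta) + 1 + bad, " of ", path,
            class = "wb_parse_error")
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 4,
              byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    wb_stop("non-numeric value at line ", sum(is_meta) + 1 + bad, " of ", path,
            class = "wb_parse_error")
  }
  fs <- as.numeric(meta$fs_hz)
  if (!length(fs) || is.na(fs) || fs <= 0)
    wb_stop("missing or invalid fs_hz header in ", path,
            class = "wb_parse_error")
  dt <- diff(m[, 1])
  bad <- which(abs(dt - 1 / fs) > 1e-4 / fs)
  if (length(bad))
    wb_stop("timestamp gap or disorder at line ", sum(is_meta) + 2 + bad[1],
            " of ", path, class = "wb_parse_error")
  xyz <- m[, 2:4, drop = FALSE]
  colnames(xyz) <- c("x", "y", "z")
  structure(list(subject_id = meta$subject_id %||% basename(path),
                 group = meta$group %||% NA_character_,
                 fs_hz = fs, duration_s = nrow(xyz) / fs, samples = xyz,
                 seed = if (!is.null(meta$seed)) as.integer(meta$seed) else NA,
                 bouts = NULL, profile = NULL),
            class = "accel_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write or read a cohort manifest
#'
#' @param cohort an `accel_cohort` whose sessions have been written with
#'   [write_session_csv()], or a data frame with columns `subject_id`,
#'   `group`, `path`.
#' @param paths session file paths, in roster order.
#' @param path manifest file path.
#' @return `read_manifest()` returns the manifest data frame.
#' @export
write_manifest <- function(cohort, paths, path) {
  df <- data.frame(subject_id = cohort$roster$subject_id,
                   group = cohort$roster$group, path = paths,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(df)))
    wb_stop("manifest must have columns subject_id, group, path",
            class = "wb_parse_error")
  df
}
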