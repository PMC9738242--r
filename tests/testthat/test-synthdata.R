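test_that("zero-movement profile yields pure unit gravity", {
  p <- subject_profile("HE", activity_scale = 0, tremor_rate = 0,
                       noise_sd_g = 0, subject_sd = 0)
  s <- generate_subject(p, days = 1, day_len_s = 30, fs_hz = 32, seed = 4)
  vm <- sqrt(rowSums(s$samples^2))
  expect_equal(vm, rep(1, nrow(s$samples)), tolerance = 1e-12)
})

test_that("generation is deterministic and day-prefix consistent", {
  p <- subject_profile("PD")
  a <- generate_subject(p, days = 2, day_len_s = 90, fs_hz = 32, seed = 7)
  b <- generate_subject(p, days = 2, day_len_s = 90, fs_hz = 32, seed = 7)
  expect_identical(a$samples, b$samples)
  one <- generate_subject(p, days = 1, day_len_s = 90, fs_hz = 32, seed = 7)
  expect_identical(one$samples, a$samples[seq_len(nrow(one$samples)), ])
  c <- generate_subject(p, days = 2, day_len_s = 90, fs_hz = 32, seed = 8)
  expect_false(identical(a$samples, c$samples))
})

test_that("tremor episodes peak in the 4-6 Hz band of rest-bout spectra", {
  p <- subject_profile("PD", tremor_rate = 1, tremor_amp_g = 0.3,
                       tremor_freq_hz = 5, subject_sd = 0)
  s <- generate_subject(p, days = 1, day_len_s = 600, fs_hz = 32, seed = 21)
  b <- s$bouts
  b <- b[b$state == "rest" & b$tremor & (b$end_s - b$start_s) > 8, ]
  expect_gt(nrow(b), 0)
  i0 <- floor(b$start_s[1] * s$fs_hz) + 2
  i1 <- floor(b$end_s[1] * s$fs_hz) - 2
  seg <- s$samples[i0:i1, , drop = FALSE]
  spec <- 0
  for (a in 1:3) {
    pg <- stats::spec.pgram(stats::ts(seg[, a] - mean(seg[, a]),
                                      frequency = s$fs_hz),
                            spans = c(3, 3), plot = FALSE, taper = 0.1)
    spec <- spec + pg$spec
  }
  peak <- pg$freq[which.max(spec)]
  expect_gte(peak, 4)
  expect_lte(peak, 6)
})

test_that("samples respect the sensor range and count invariants", {
  p <- subject_profile("PD", tremor_amp_g = 30, tremor_rate = 1)
  s <- generate_subject(p, days = 1, day_len_s = 60, fs_hz = 32, seed = 2,
                        range_g = 8)
  expect_true(all(abs(s$samples) <= 8))
  expect_equal(nrow(s$samples), round(60 * 32))
  expect_false(anyNA(s$samples))
})

test_that("invalid generation configs are rejected", {
  p <- subject_profile("HE")
  expect_error(generate_subject(p, days = 0, day_len_s = 60, fs_hz = 32),
               class = "wb_invalid_config")
  expect_error(generate_subject(p, days = 1, day_len_s = -5, fs_hz = 32),
               class = "wb_invalid_config")
  expect_error(subject_profile("PD", tremor_rate = 1.5),
               class = "wb_invalid_config")
  expect_error(subject_profile("PD", activity_scale = -1),
               class = "wb_invalid_config")
})

test_that("default cohort matches the study composition, empty allowed", {
  cfg <- cohort_config(days = 1, day_len_s = 10, fs_hz = 4)
  roster <- generate_cohort(cfg)$roster
  expect_equal(sum(roster$group == "HE"), 32)
  expect_equal(sum(roster$group == "PD"), 28)
  expect_equal(length(unique(roster$subject_id)), 60)
  empty <- generate_cohort(cohort_config(n_he = 0, n_pd = 0, days = 1,
                                         day_len_s = 10, fs_hz = 4))
  expect_length(empty$sessions, 0)
})

test_that("cohorts are reproducible from the master seed", {
  cfg <- tiny_config(seed = 5, n = 2, day_len_s = 30)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(lapply(a$sessions, `[[`, "samples"),
                   lapply(b$sessions, `[[`, "samples"))
})

test_that("session CSV round-trips and rejects corrupted files", {
  s <- tiny_session(seed = 3, day_len_s = 10, fs_hz = 16)
  f <- withr::local_tempfile(fileext = ".csv")
  write_session_csv(s, f)
  r <- read_session_csv(f)
  expect_equal(r$subject_id, s$subject_id)
  expect_equal(r$group, s$group)
  expect_equal(r$fs_hz, s$fs_hz)
  expect_equal(r$samples, s$samples, tolerance = 1e-8)

  lines <- readLines(f)
  writeLines(lines[-10], f)  # drop a data row -> timestamp gap
  expect_error(read_session_csv(f), "line", class = "wb_parse_error")
})

test_that("handcrafted 3-line session file parses to stated values", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# subject_id: H01", "# group: HE", "# fs_hz: 10",
               "timestamp,x,y,z",
               "0.0,0.1,0.2,0.9", "0.1,0.2,0.3,1.0", "0.2,0.3,0.4,1.1"), f)
  s <- read_session_csv(f)
  expect_equal(nrow(s$samples), 3)
  expect_equal(s$samples[, "x"], c(0.1, 0.2, 0.3))
  expect_equal(unname(s$samples[2, "z"]), 1.0)
  expect_equal(s$duration_s, 0.3)

  writeLines(c("# fs_hz: 10", "timestamp,x,y,z", "0.0,0.1,oops,0.9"), f)
  expect_error(read_session_csv(f), "line 3", class = "wb_parse_error")
})

test_that("manifest round-trips", {
  co <- generate_cohort(tiny_config(n = 1, day_len_s = 5, fs_hz = 8,
                                    windows = 3))
  dir <- withr::local_tempdir()
  paths <- file.path(dir, paste0(co$roster$subject_id, ".csv"))
  for (i in seq_along(co$sessions)) write_session_csv(co$sessions[[i]], paths[i])
  mpath <- file.path(dir, "manifest.csv")
  write_manifest(co, paths, mpath)
  mf <- read_manifest(mpath)
  expect_equal(mf$subject_id, co$roster$subject_id)
  expect_equal(mf$group, co$roster$group)
})

test_that("raising tremor amplitude raises rest-bout acceleration range", {
  mean_rest_range <- function(amp, seed) {
    p <- subject_profile("PD", tremor_rate = 1, tremor_amp_g = amp,
                         subject_sd = 0, day_effect_sd = 0)
    s <- generate_subject(p, days = 1, day_len_s = 300, fs_hz = 32,
                          seed = seed)
    b <- s$bouts[s$bouts$state == "rest", ]
    vals <- vapply(seq_len(nrow(b)), function(i) {
      i0 <- floor(b$start_s[i] * s$fs_hz) + 1
      i1 <- floor(b$end_s[i] * s$fs_hz)
      if (i1 - i0 < 32) return(NA_real_)
      mean(acceleration_range(s$samples[i0:i1, , drop = FALSE]))
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  amps <- c(0.05, 0.2, 0.5)
  curves <- sapply(1:3, function(seed)
    vapply(amps, mean_rest_range, numeric(1), seed = seed))
  avg <- rowMeans(curves)
  expect_true(all(diff(avg) > 0))
})

test_that("null cohorts reject group differences at the nominal rate", {
  # 100 null cohorts; two-sample t-test on the subject-level mean vector
  # magnitude at 60 s.  With alpha = 0.05 the rejection count is Binomial
  # (100, 0.05); its 99.5% quantile is 11.
  rejections <- 0
  for (i in 1:100) {
    cfg <- null_cohort_config(tiny_config(seed = 1000 + i, n = 4,
                                          day_len_s = 120, fs_hz = 16,
                                          windows = 60))
    cd <- cohort_descriptors(cfg)
    x <- stat_features(cd)
    pval <- t.test(x[cd$roster$group == "HE", "vm_60s"],
                   x[cd$roster$group == "PD", "vm_60s"])$p.value
    rejections <- rejections + (pval < 0.05)
  }
  expect_lte(rejections, 11)
})
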