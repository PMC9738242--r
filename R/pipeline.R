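#' End-to-end workflow: best feature engineering and windowing strategy
#'
#' Chains the full first workflow of the study on a synthetic cohort:
#' simulate, segment, compute descriptors, build per-strategy statistical
#' and word feature sets (including GA-reduced sets), cross-validate
#' every set across classifiers, compare windowing strategies (ANOVA +
#' Tukey on the word sets) and feature-engineering methods (paired
#' t-test, reduced set vs reduced set pooled over classifiers).  All
#' artifacts (config, feature tables, vocabularies, per-run results,
#' summary tables, comparison reports) are written to `outdir` with
#' deterministic content, so two runs with the same configuration and
#' seed produce byte-identical artifact sets.
#'
#' @param config a [cohort_config()].
#' @param outdir output directory (created if needed).
#' @param n_runs,folds CV settings.
#' @param classifiers classifier ids to evaluate.
#' @param k_candidates,subsample,restarts vocabulary settings.
#' @param ga,ga_classifiers,ga_runs,ga_folds GA budget for the reduced
#'   sets.
#' @param seed master analysis seed (independent of the cohort seed).
#' @return Invisibly, a list with the word/stat `wb_results`, the two
#'   comparison reports and the output paths.
#' @export
run_method_comparison <- function(config, outdir, n_runs = 100, folds = 10,
                                  classifiers = wb_classifiers(),
                                  k_candidates = c(4, 8, 12, 16, 20, 24, 28, 32),
                                  subsample = 20000, restarts = 5,
                                  ga = ga_config(),
                                  ga_classifiers = classifiers,
                                  ga_runs = 1, ga_folds = 5, seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_config_yaml(config, file.path(outdir, "config.yaml"),
                    extra = list(n_runs = n_runs, folds = folds,
                                 seed = seed, classifiers = classifiers))
  cd <- cohort_descriptors(config)
  log_segment_counts(cd, config, file.path(outdir, "segments.csv"))

  wsets <- word_feature_sets(cd, k_candidates = k_candidates, seed = seed,
                             subsample = subsample, restarts = restarts,
                             ga = ga, ga_classifiers = ga_classifiers,
                             ga_runs = ga_runs, ga_folds = ga_folds)
  ssets <- stat_feature_sets(cd, seed = seed, ga = ga,
                             ga_classifiers = ga_classifiers,
                             ga_runs = ga_runs, ga_folds = ga_folds)
  for (w in names(attr(wsets, "vocabularies")))
    write_vocabulary_json(attr(wsets, "vocabularies")[[w]],
                          file.path(outdir, sprintf("vocabulary_%ss.json", w)))
  write.csv(data.frame(subject_id = rownames(wsets$all), wsets$all,
                       check.names = FALSE),
            file.path(outdir, "word_features.csv"), row.names = FALSE)
  write.csv(data.frame(subject_id = rownames(ssets$all), ssets$all,
                       check.names = FALSE),
            file.path(outdir, "stat_features.csv"), row.names = FALSE)

  labels <- cd$roster$group
  wres <- evaluate_feature_sets(wsets, labels, classifiers = classifiers,
                                n_runs = n_runs, folds = folds, seed = seed)
  sres <- evaluate_feature_sets(ssets, labels, classifiers = classifiers,
                                n_runs = n_runs, folds = folds, seed = seed)
  write_results_csv(wres, file.path(outdir, "word_results.csv"))
  write_results_csv(sres, file.path(outdir, "stat_results.csv"))
  write.csv(format_results_table(wres),
            file.path(outdir, "word_summary.csv"), row.names = FALSE)
  write.csv(format_results_table(sres),
            file.path(outdir, "stat_summary.csv"), row.names = FALSE)

  svm_cl <- if ("svm" %in% classifiers) "svm" else classifiers[1]
  win_cmp <- compare_windowing(lapply(wres$results, function(r)
    r[[svm_cl]]$accuracy))
  stat_pool <- unlist(lapply(sres$results$all_reduced,
                             function(cv) cv$accuracy))
  word_pool <- unlist(lapply(wres$results$all_reduced,
                             function(cv) cv$accuracy))
  meth_cmp <- compare_methods(stat_pool, word_pool, paired = TRUE)
  jsonlite::write_json(
    list(windowing = unclass_report(win_cmp),
         methods = unclass_report(meth_cmp)),
    file.path(outdir, "comparisons.json"), digits = NA, auto_unbox = TRUE,
    force = TRUE)

  invisible(list(word = wres, stat = sres, windowing = win_cmp,
                 methods = meth_cmp, sets = list(word = wsets, stat = ssets),
                 outdir = outdir))
}

#' End-to-end workflow: optimal amount of data in days
#'
#' Runs [days_analysis()] and writes its artifacts (per-day accuracies,
#' comparison report, Dunn matrix rendering) to `outdir`.
#'
#' @inheritParams run_method_comparison
#' @param ... passed to [days_analysis()].
#' @return Invisibly, the `wb_days` object.
#' @export
run_days_analysis <- function(config, outdir, seed = 1, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_config_yaml(config, file.path(outdir, "config.yaml"),
                    extra = list(seed = seed))
  res <- days_analysis(config, seed = seed, ...)
  acc <- res$accuracy_by_day
  write.csv(data.frame(day = rep(names(acc), lengths(acc)),
                       accuracy = unlist(acc, use.names = FALSE)),
            file.path(outdir, "day_accuracies.csv"), row.names = FALSE)
  jsonlite::write_json(unclass_report(res$comparison),
                       file.path(outdir, "days_comparison.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  if (!res$comparison$parametric)
    write.csv(dunn_matrix(res$comparison$pairwise),
              file.path(outdir, "dunn_matrix.csv"))
  invisible(res)
}

write_results_csv <- function(res, path) {
  rows <- do.call(rbind, lapply(names(res$results), function(s)
    do.call(rbind, lapply(names(res$results[[s]]), function(cl) {
      cv <- res$results[[s]][[cl]]
      data.frame(set = s, classifier = cl, run = seq_along(cv$accuracy),
                 accuracy = cv$accuracy, auc = cv$auc,
                 stringsAsFactors = FALSE)
    }))))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

write_config_yaml <- function(config, path, extra = list()) {
  obj <- lapply(unclass(config), function(v)
    if (inherits(v, "wb_profile")) unclass(v) else v)
  yaml::write_yaml(c(obj, list(analysis = extra)), path)
  invisible(path)
}

#' Read a cohort configuration from a YAML file
#'
#' Inverse of the config serialisation performed by the workflow
#' drivers; unknown keys are ignored.
#'
#' @param path YAML file.
#' @return A `wb_cohort_config`.
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  mk_prof <- function(p, group) do.call(subject_profile, c(list(group = group),
    p[setdiff(names(p), "group")]))
  cohort_config(
    n_he = obj$n_he %||% 32, n_pd = obj$n_pd %||% 28,
    days = obj$days %||% 7, preset = obj$preset %||% "desk",
    day_len_s = obj$day_len_s, fs_hz = obj$fs_hz,
    he = if (!is.null(obj$he)) mk_prof(obj$he, "HE") else subject_profile("HE"),
    pd = if (!is.null(obj$pd)) mk_prof(obj$pd, "PD") else subject_profile("PD"),
    windows = obj$windows %||% c(3, 10, 60, 300, 900),
    seed = obj$seed %||% 1)
}

unclass_report <- function(x) {
  out <- unclass(x)
  out$pairwise <- if (!is.null(out$pairwise) && is.matrix(out$pairwise))
    as.data.frame(out$pairwise) else out$pairwise
  out
}

log_segment_counts <- function(cd, config, path) {
  df <- do.call(rbind, lapply(names(cd$windows), function(w) {
    counts <- tabulate(cd$windows[[w]]$subject, nbins = nrow(cd$roster))
    data.frame(window_s = as.numeric(w), subject_id = cd$roster$subject_id,
               n_segments = counts, stringsAsFactors = FALSE)
  }))
  # bookkeeping invariant: per-subject counts obey the closed form
  expected <- segment_count(config$days * config$day_len_s,
                            as.numeric(df$window_s[1]))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Hash a run's artifact files
#'
#' MD5 of every regular file under `dir` (sorted relative paths), for
#' checking that identically configured runs reproduce identical
#' artifacts.
#'
#' @param dir artifact directory.
#' @return Named character vector of MD5 hashes.
#' @export
artifact_hashes <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  h <- tools::md5sum(file.path(dir, files))
  names(h) <- files
  h
}
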