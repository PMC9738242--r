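#' Evaluate feature sets across classifiers
#'
#' Runs [run_cv()] for every (feature set, classifier) combination with a
#' shared seed, so results are paired by (classifier, run) across sets.
#'
#' @param sets named list of feature matrices with identical rownames
#'   (subject ids).
#' @param labels 2-level group factor in row order.
#' @param classifiers classifier ids.
#' @param n_runs,folds,seed,stratified CV settings.
#' @return A `wb_results` object: nested `wb_cv` results plus a summary
#'   data frame (`set`, `n_features`, `classifier`, `mean_accuracy`,
#'   `sd_accuracy`, `mean_auc`).
#' @export
evaluate_feature_sets <- function(sets, labels,
                                  classifiers = wb_classifiers(),
                                  n_runs = 100, folds = 10, seed = 1,
                                  stratified = TRUE) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)))
  ids <- rownames(sets[[1]])
  for (s in names(sets)) {
    if (!identical(rownames(sets[[s]]), ids))
      wb_stop("subject ids differ between feature sets (set '", s, "')",
              class = "wb_invalid_config")
  }
  labels <- factor(labels)
  results <- lapply(sets, function(x) {
    out <- lapply(classifiers, function(cl)
      run_cv(x, labels, cl, n_runs = n_runs, folds = folds, seed = seed,
             stratified = stratified))
    names(out) <- classifiers
    out
  })
  summ <- do.call(rbind, lapply(names(results), function(s)
    do.call(rbind, lapply(classifiers, function(cl) {
      cv <- results[[s]][[cl]]
      data.frame(set = s, n_features = ncol(sets[[s]]), classifier = cl,
                 mean_accuracy = mean(cv$accuracy),
                 sd_accuracy = sd(cv$accuracy),
                 mean_auc = mean(cv$auc, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))))
  structure(list(results = results, summary = summ, n_runs = n_runs,
                 folds = folds, seed = seed, classifiers = classifiers),
            class = "wb_results")
}

#' @export
print.wb_results <- function(x, digits = 1, ...) {
  cat(sprintf("<wb_results: %d sets x %d classifiers, %d x %d-fold CV>\n",
              length(x$results), length(x$classifiers), x$n_runs, x$folds))
  print(format_results_table(x, digits = digits))
  invisible(x)
}

#' Accuracy table formatted as mean +/- sd percent
#'
#' Renders a [evaluate_feature_sets()] summary in the familiar
#' one-row-per-feature-set layout with `mean +/- sd` percentage entries
#' per classifier.
#'
#' @param x a `wb_results`.
#' @param digits decimal places.
#' @return A data frame of formatted strings.
#' @export
format_results_table <- function(x, digits = 1) {
  s <- x$summary
  sets <- unique(s$set)
  out <- data.frame(set = sets,
                    features = vapply(sets, function(st)
                      s$n_features[s$set == st][1], numeric(1)))
  for (cl in x$classifiers)
    out[[cl]] <- vapply(sets, function(st) {
      row <- s[s$set == st & s$classifier == cl, ]
      sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
              100 * row$mean_accuracy, 100 * row$sd_accuracy)
    }, character(1))
  rownames(out) <- NULL
  out
}

#' @export
plot.wb_results <- function(x, classifier = x$classifiers[1], ...) {
  acc <- lapply(x$results, function(r) 100 * r[[classifier]]$accuracy)
  graphics::boxplot(acc, ylab = sprintf("%s accuracy (%%)", classifier),
                    las = 2, ...)
  invisible(x)
}

#' Build the per-strategy / combined / reduced feature-set families
#'
#' Reproduces the experiment layout of the study: one feature set per
#' windowing strategy, the combination of all strategies, and a reduced
#' set obtained by GA feature selection on the combination.  Works for
#' both representations: `word_feature_sets()` uses term-frequency
#' documents, `stat_feature_sets()` the averaged statistical features.
#'
#' @param cd a [cohort_descriptors()] result.
#' @param k_candidates,seed,subsample,restarts vocabulary settings (word
#'   features only).
#' @param reduce also compute the GA-reduced set (`"all_reduced"`).
#' @param ga,ga_classifiers,ga_runs,ga_folds GA budget for the reduced
#'   set.
#' @return Named list of feature matrices: `w<S>s` (or `s<S>s`), `all`,
#'   and optionally `all_reduced`.  Word-feature output carries the
#'   vocabularies of the combined set as attribute `"vocabularies"`.
#' @export
word_feature_sets <- function(cd, k_candidates = c(4, 8, 12, 16, 20, 24, 28, 32),
                              seed = 1, subsample = 20000, restarts = 5,
                              reduce = TRUE, ga = ga_config(),
                              ga_classifiers = wb_classifiers(),
                              ga_runs = 1, ga_folds = 5) {
  all_x <- word_features(cd, k_candidates = k_candidates, seed = seed,
                         subsample = subsample, restarts = restarts)
  vocabs <- attr(all_x, "vocabularies")
  sets <- list()
  for (w in names(cd$windows)) {
    cols <- grep(sprintf("^w%ss_", w), colnames(all_x))
    sets[[sprintf("w%ss", w)]] <- all_x[, cols, drop = FALSE]
  }
  sets$all <- all_x
  if (reduce) {
    mask <- ga_select(all_x, cd$roster$group, ga = ga,
                      classifiers = ga_classifiers, n_runs = ga_runs,
                      folds = ga_folds, seed = derive_seed(seed, 97))
    sets$all_reduced <- all_x[, mask$mask, drop = FALSE]
    attr(sets, "mask") <- mask
  }
  attr(sets, "vocabularies") <- vocabs
  sets
}

#' @rdname word_feature_sets
#' @export
stat_feature_sets <- function(cd, seed = 1, reduce = TRUE, ga = ga_config(),
                              ga_classifiers = wb_classifiers(),
                              ga_runs = 1, ga_folds = 5) {
  all_x <- stat_features(cd)
  sets <- list()
  for (w in names(cd$windows)) {
    cols <- grep(sprintf("_%ss$", w), colnames(all_x))
    sets[[sprintf("s%ss", w)]] <- all_x[, cols, drop = FALSE]
  }
  sets$all <- all_x
  if (reduce) {
    mask <- ga_select(all_x, cd$roster$group, ga = ga,
                      classifiers = ga_classifiers, n_runs = ga_runs,
                      folds = ga_folds, seed = derive_seed(seed, 98))
    sets$all_reduced <- all_x[, mask$mask, drop = FALSE]
    attr(sets, "mask") <- mask
  }
  sets
}
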