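#' Repeated k-fold cross-validated classification
#'
#' Runs `n_runs` independent shuffled (by default stratified) `folds`-fold
#' cross-validations of one classifier.  Per run, held-out predictions are
#' pooled over the folds into one accuracy value, and the AUC is computed
#' from the pooled held-out decision scores; the study protocol is 100
#' runs of 10-fold CV.  Deterministic given `seed`.
#'
#' @param x feature matrix (rows = subjects) -- ignored when `builder` is
#'   given.
#' @param labels 2-level factor (or coercible) of group labels.
#' @param classifier one of [wb_classifiers()].
#' @param n_runs,folds repetition count and fold count.
#' @param seed RNG seed.
#' @param stratified stratify fold assignment by class (default); plain
#'   splitting is available for sensitivity checks.
#' @param builder optional function `(train_idx, test_idx) ->
#'   list(train =, test =)` returning feature matrices built using only
#'   training subjects -- the leak-free route for fold-scoped vocabulary
#'   features.
#' @return A `wb_cv` object: per-run `accuracy` and `auc` vectors plus
#'   settings.
#' @examples
#' x <- matrix(rnorm(40), 20)
#' y <- rep(c("a", "b"), 10)
#' run_cv(x, y, "svm", n_runs = 3, folds = 5, seed = 1)
#' @export
run_cv <- function(x, labels, classifier = "svm", n_runs = 100, folds = 10,
                   seed = 1, stratified = TRUE, builder = NULL) {
  labels <- factor(labels)
  n <- length(labels)
  if (nlevels(labels) != 2)
    wb_stop("labels must have exactly 2 classes present",
            class = "wb_invalid_config")
  if (folds > n)
    wb_stop("more folds than subjects", class = "wb_invalid_config")
  if (is.null(builder)) {
    x <- as.matrix(x)
    if (nrow(x) != n)
      wb_stop("feature rows do not match labels", class = "wb_invalid_config")
    builder <- function(tr, te) list(train = x[tr, , drop = FALSE],
                                     test = x[te, , drop = FALSE])
  }
  classifier <- match.arg(classifier, wb_classifiers())
  acc <- auc <- numeric(n_runs)
  with_seed(seed, {
    for (run in seq_len(n_runs)) {
      fold_id <- integer(n)
      if (stratified) {
        for (lv in levels(labels)) {
          idx <- which(labels == lv)
          fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
        }
      } else fold_id <- sample(rep_len(seq_len(folds), n))
      pred <- factor(rep(levels(labels)[1], n), levels = levels(labels))
      score <- numeric(n)
      for (f in seq_len(folds)) {
        te <- which(fold_id == f)
        tr <- which(fold_id != f)
        if (!length(te)) next
        if (nlevels(droplevels(labels[tr])) < 2)
          wb_stop("training fold lost a class; reduce folds",
                  class = "wb_invalid_config")
        feats <- builder(tr, te)
        fp <- fit_predict(classifier, feats$train, labels[tr], feats$test)
        pred[te] <- fp$class
        score[te] <- fp$score
      }
      acc[run] <- mean(pred == labels)
      auc[run] <- auc_rank(score, labels)
    }
  })
  structure(list(accuracy = acc, auc = auc, classifier = classifier,
                 n_runs = n_runs, folds = folds, seed = seed,
                 stratified = stratified, n = n,
                 hyperparameters = wb_hyperparameters()[[classifier]]),
            class = "wb_cv")
}

#' @export
print.wb_cv <- function(x, ...) {
  cat(sprintf(
    "<wb_cv %s: %d x %d-fold, accuracy %.1f +/- %.1f%%, AUC %.2f>\n",
    x$classifier, x$n_runs, x$folds, 100 * mean(x$accuracy),
    100 * sd(x$accuracy), mean(x$auc, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.wb_cv <- function(object, ...) {
  c(mean_accuracy = mean(object$accuracy), sd_accuracy = sd(object$accuracy),
    mean_auc = mean(object$auc, na.rm = TRUE))
}
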