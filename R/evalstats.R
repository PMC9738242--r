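#' Compare windowing strategies by one-way ANOVA with Tukey HSD
#'
#' Applies the study's windowing comparison to per-strategy accuracy
#' samples: a Shapiro-Wilk normality gate per group, one-way ANOVA, and
#' Tukey's HSD pairwise comparisons at the given confidence level.
#'
#' @param acc_list named list (>= 3 groups) of accuracy vectors (>= 2
#'   observations each).
#' @param alpha significance level.
#' @return A `wb_comparison` with the F statistic and degrees of freedom,
#'   p-value, per-group Shapiro p-values, the Tukey pairwise matrix and
#'   the significant pairs.
#' @export
compare_windowing <- function(acc_list, alpha = 0.05) {
  stopifnot(is.list(acc_list), !is.null(names(acc_list)))
  if (length(acc_list) < 3)
    wb_stop("need at least 3 groups", class = "wb_invalid_config")
  if (any(lengths(acc_list) < 2))
    wb_stop("each group needs at least 2 observations",
            class = "wb_invalid_config")
  if (all(vapply(acc_list, function(v) var(v) == 0, logical(1))))
    wb_stop("all groups are constant; comparison degenerate",
            class = "wb_degenerate")
  df <- data.frame(acc = unlist(acc_list, use.names = FALSE),
                   set = factor(rep(names(acc_list), lengths(acc_list)),
                                levels = names(acc_list)))
  shap <- vapply(acc_list, function(v) {
    if (length(unique(v)) < 3 || length(v) < 3) return(NA_real_)
    shapiro.test(if (length(v) > 5000) sample(v, 5000) else v)$p.value
  }, numeric(1))
  fit <- aov(acc ~ set, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$set
  sig <- rownames(tk)[tk[, "p adj"] < alpha]
  structure(list(test = "one-way ANOVA + Tukey HSD",
                 statistic = an[["F value"]][1],
                 df = c(df1 = an[["Df"]][1], df2 = an[["Df"]][2]),
                 p_value = an[["Pr(>F)"]][1], shapiro_p = shap,
                 pairwise = tk, significant_pairs = sig, alpha = alpha),
            class = "wb_comparison")
}

#' Compare feature-engineering methods by paired t-test
#'
#' Tests whether word-document features outperform averaged statistical
#' features: a one-sided paired t-test of `word - stat > 0` on accuracy
#' values paired by (classifier, run), plus a one-sided Welch two-sample
#' test as a sensitivity analysis.  When all paired differences are zero
#' the paired statistic is reported as t = 0, p = 0.5 (the degenerate
#' no-evidence case).
#'
#' @param stat_acc,word_acc accuracy vectors; equal length when
#'   `paired = TRUE` (study layout: 6 classifiers x 100 runs = 600 per
#'   method).
#' @param paired pair the values (default) or only run the Welch test.
#' @param alpha significance level.
#' @return A `wb_comparison` with both tests' statistics and p-values.
#' @export
compare_methods <- function(stat_acc, word_acc, paired = TRUE, alpha = 0.05) {
  if (paired && length(stat_acc) != length(word_acc))
    wb_stop("paired comparison needs equal-length accuracy vectors",
            class = "wb_invalid_config")
  out <- list(test = "one-sided t-test (word > statistical)", alpha = alpha,
              mean_stat = mean(stat_acc), mean_word = mean(word_acc))
  if (paired) {
    d <- word_acc - stat_acc
    if (all(d == 0)) {
      out$paired <- list(statistic = 0, df = length(d) - 1, p_value = 0.5)
    } else if (sd(d) == 0) {
      # constant non-zero shift: infinite evidence in the shift's direction
      out$paired <- list(statistic = sign(mean(d)) * Inf,
                         df = length(d) - 1,
                         p_value = if (mean(d) > 0) 0 else 1)
    } else {
      tt <- t.test(word_acc, stat_acc, paired = TRUE, alternative = "greater")
      out$paired <- list(statistic = unname(tt$statistic),
                         df = unname(tt$parameter), p_value = tt$p.value)
    }
  }
  if (var(word_acc) > 0 || var(stat_acc) > 0) {
    wt <- t.test(word_acc, stat_acc, alternative = "greater")
    out$welch <- list(statistic = unname(wt$statistic),
                      df = unname(wt$parameter), p_value = wt$p.value)
  } else out$welch <- list(statistic = 0, df = NA_real_, p_value = 0.5)
  out$p_value <- if (paired) out$paired$p_value else out$welch$p_value
  structure(out, class = "wb_comparison")
}

#' Dunn's post-hoc pairwise test
#'
#' Rank-based pairwise comparisons following a Kruskal-Wallis test, with
#' the tie-corrected z statistic
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t)` over tie groups, and Bonferroni adjustment of
#' the two-sided p-values (capped at 1).
#'
#' @param x numeric values.
#' @param g grouping factor.
#' @param p_adjust adjustment method (see [stats::p.adjust()]).
#' @return Data frame with one row per unordered group pair: `group1`,
#'   `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(x, g, p_adjust = "bonferroni") {
  g <- factor(g)
  stopifnot(length(x) == length(g), nlevels(g) >= 2)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- combn(levels(g), 2)
  z <- apply(pairs, 2, function(p) {
    i <- match(p[1], levels(g)); j <- match(p[2], levels(g))
    (rbar[[i]] - rbar[[j]]) /
      sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}

#' Lower-triangular rendering of a Dunn pairwise table
#'
#' @param dunn result of [dunn_test()].
#' @return Character matrix (rows = later groups, columns = earlier
#'   groups) with `z` over adjusted `p` entries, mirroring the familiar
#'   pairwise-comparison layout.
#' @export
dunn_matrix <- function(dunn) {
  gl <- unique(c(dunn$group1, dunn$group2))
  m <- matrix("", length(gl) - 1, length(gl) - 1,
              dimnames = list(gl[-1], gl[-length(gl)]))
  for (r in seq_len(nrow(dunn))) {
    m[dunn$group2[r], dunn$group1[r]] <-
      sprintf("%.2f / p=%.4g%s", dunn$z[r], dunn$p_adj[r],
              if (dunn$p_adj[r] < 0.05) " *" else "")
  }
  m
}

#' Compare accuracies across days of data
#'
#' The statistical half of the days-of-data analysis.  Normality
#' (Shapiro-Wilk per group) and homogeneity (Levene) gates choose the
#' path: one-way ANOVA with Tukey HSD when both hold, otherwise
#' Kruskal-Wallis with Dunn-Bonferroni post hoc.  Reports the pairwise
#' matrix and the minimal number of days whose accuracy is not
#' significantly different from the maximal-days baseline.
#'
#' @param acc_by_day named list (`day1` ... `day7`) of accuracy vectors.
#' @param alpha significance level.
#' @param force_nonparametric skip the gates and use the rank-based path.
#' @return A `wb_comparison` with gate outcomes, omnibus statistic,
#'   pairwise results and `minimal_days`.
#' @export
compare_days <- function(acc_by_day, alpha = 0.05,
                         force_nonparametric = FALSE) {
  stopifnot(is.list(acc_by_day), length(acc_by_day) >= 2)
  days <- names(acc_by_day)
  x <- unlist(acc_by_day, use.names = FALSE)
  g <- factor(rep(days, lengths(acc_by_day)), levels = days)
  shap <- vapply(acc_by_day, function(v) {
    if (length(unique(v)) < 3 || length(v) < 3) return(NA_real_)
    shapiro.test(if (length(v) > 5000) sample(v, 5000) else v)$p.value
  }, numeric(1))
  lev <- tryCatch(car::leveneTest(x, g)[["Pr(>F)"]][1], error = function(e) NA)
  normal_ok <- all(is.na(shap) | shap > alpha)
  homo_ok <- !is.na(lev) && lev > alpha
  parametric <- normal_ok && homo_ok && !force_nonparametric
  if (parametric) {
    fit <- aov(x ~ g)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
    pw <- data.frame(group1 = sub("-.*", "", rownames(tk)),
                     group2 = sub(".*-", "", rownames(tk)),
                     z = NA_real_, p = tk[, "p adj"], p_adj = tk[, "p adj"],
                     stringsAsFactors = FALSE)
    omnibus <- list(test = "one-way ANOVA", statistic = an[["F value"]][1],
                    df = c(df1 = an[["Df"]][1], df2 = an[["Df"]][2]),
                    p_value = an[["Pr(>F)"]][1])
  } else {
    kw <- kruskal.test(x, g)
    pw <- dunn_test(x, g)
    omnibus <- list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
                    df = unname(kw$parameter), p_value = kw$p.value)
  }
  baseline <- days[length(days)]
  vs_base <- vapply(days[-length(days)], function(d) {
    row <- (pw$group1 == d & pw$group2 == baseline) |
      (pw$group1 == baseline & pw$group2 == d)
    pw$p_adj[row]
  }, numeric(1))
  not_diff <- c(names(vs_base)[vs_base > alpha], baseline)
  minimal <- not_diff[1]
  structure(list(test = omnibus$test, statistic = omnibus$statistic,
                 df = omnibus$df, p_value = omnibus$p_value,
                 shapiro_p = shap, levene_p = lev, parametric = parametric,
                 pairwise = pw, baseline = baseline,
                 p_vs_baseline = vs_base, minimal_days = minimal,
                 alpha = alpha),
            class = "wb_comparison")
}

#' @export
print.wb_comparison <- function(x, ...) {
  cat("<wb_comparison: ", x$test, ">\n", sep = "")
  if (!is.null(x$statistic))
    cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  if (!is.null(x$paired))
    cat(sprintf("  paired: t = %.3f, df = %.1f, p = %.3g\n",
                x$paired$statistic, x$paired$df, x$paired$p_value))
  if (!is.null(x$welch))
    cat(sprintf("  Welch:  t = %.3f, df = %.1f, p = %.3g\n",
                x$welch$statistic, x$welch$df, x$welch$p_value))
  if (!is.null(x$minimal_days))
    cat("  minimal days equivalent to baseline: ", x$minimal_days, "\n")
  if (!is.null(x$significant_pairs) && length(x$significant_pairs))
    cat("  significant pairs:", paste(x$significant_pairs, collapse = ", "),
        "\n")
  invisible(x)
}

#' Full days-of-data experiment
#'
#' For each day count `d = 1 .. days`, generates (or truncates to) the
#' first `d` day units of every subject, rebuilds the word-feature
#' pipeline from scratch (per-day-count vocabularies), cross-validates
#' the chosen classifier, and finally compares the per-day accuracy
#' distributions with [compare_days()].
#'
#' @param config a [cohort_config()].
#' @param windows window lengths (s); must fit inside one day unit.
#' @param classifier classifier id (study choice: RBF SVM).
#' @param n_runs,folds,cv_seed CV settings.
#' @param k_candidates,subsample,restarts,seed vocabulary settings.
#' @param alpha significance level.
#' @param force_nonparametric passed to [compare_days()].
#' @return A `wb_days` object: `accuracy_by_day`, the `comparison`, and
#'   the settings.
#' @export
days_analysis <- function(config, windows = NULL, classifier = "svm",
                          n_runs = 100, folds = 10, cv_seed = 1,
                          k_candidates = c(4, 8, 12, 16, 20, 24, 28, 32),
                          subsample = 20000, restarts = 5, seed = 1,
                          alpha = 0.05, force_nonparametric = FALSE) {
  stopifnot(inherits(config, "wb_cohort_config"))
  if (is.null(windows)) windows <- config$windows
  if (max(windows) > config$day_len_s)
    wb_stop("largest window exceeds one day unit",
            class = "wb_invalid_config")
  acc <- list()
  for (d in seq_len(config$days)) {
    cd <- cohort_descriptors(config, windows = windows, days = d)
    # one vocabulary seed for all day counts: conditions differ only in
    # the amount of data, not in subsampling noise
    x <- word_features(cd, k_candidates = k_candidates,
                       seed = derive_seed(seed, 1), subsample = subsample,
                       restarts = restarts)
    cv <- run_cv(x, cd$roster$group, classifier, n_runs = n_runs,
                 folds = folds, seed = cv_seed)
    acc[[paste0("day", d)]] <- cv$accuracy
  }
  cmp <- compare_days(acc, alpha = alpha,
                      force_nonparametric = force_nonparametric)
  structure(list(accuracy_by_day = acc, comparison = cmp,
                 classifier = classifier, n_runs = n_runs, folds = folds,
                 windows = windows, seed = seed),
            class = "wb_days")
}

#' @export
print.wb_days <- function(x, ...) {
  means <- vapply(x$accuracy_by_day, mean, numeric(1))
  cat("<wb_days: mean accuracy by day>\n")
  print(round(100 * means, 1))
  print(x$comparison)
  invisible(x)
}
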