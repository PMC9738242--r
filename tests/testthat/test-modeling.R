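make_xy <- function(n = 30, p = 4, sep = 0, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("HE", "PD"), length.out = n))
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[, 1] <- x[, 1] + sep * (y == "PD")
  list(x = x, y = y)
}

test_that("separable data gives perfect SVM accuracy every run", {
  set.seed(1)
  y <- factor(rep(c("HE", "PD"), each = 15))
  x <- cbind(f1 = 4 * (y == "PD") + rnorm(30, sd = 0.05),
             f2 = rnorm(30, sd = 0.05))
  cv <- run_cv(x, y, "svm", n_runs = 10, folds = 5, seed = 3)
  expect_equal(cv$accuracy, rep(1, 10))
  expect_equal(cv$auc, rep(1, 10))
})

test_that("label-shuffled features stay inside the chance band", {
  # labels re-shuffled independently of the features for each replicate;
  # the pooled mean accuracy then estimates the chance rate 0.5 with a
  # 99% binomial band 0.5 +/- 2.576 * sqrt(0.25 / 40) for n = 40
  d <- make_xy(n = 40, p = 6, sep = 3, seed = 2)
  set.seed(11)
  means <- replicate(10, {
    y_perm <- sample(d$y)
    mean(run_cv(d$x, y_perm, "svm", n_runs = 5, folds = 10,
                seed = sample.int(1e6, 1))$accuracy)
  })
  half_width <- 2.576 * sqrt(0.25 / 40)
  expect_gt(mean(means), 0.5 - half_width)
  expect_lt(mean(means), 0.5 + half_width)
})

test_that("cross-validation is seeded, stratified and validated", {
  d <- make_xy(n = 24, sep = 1, seed = 3)
  a <- run_cv(d$x, d$y, "knn", n_runs = 5, folds = 6, seed = 9)
  b <- run_cv(d$x, d$y, "knn", n_runs = 5, folds = 6, seed = 9)
  expect_identical(a$accuracy, b$accuracy)
  expect_identical(a$auc, b$auc)
  c2 <- run_cv(d$x, d$y, "knn", n_runs = 5, folds = 6, seed = 10)
  expect_false(identical(a$accuracy, c2$accuracy))

  perm <- run_cv(d$x[, c(3, 1, 4, 2)], d$y, "knn", n_runs = 5, folds = 6,
                 seed = 9)
  expect_equal(perm$accuracy, a$accuracy)

  expect_error(run_cv(d$x, factor(rep("HE", 24)), "svm"),
               class = "wb_invalid_config")
  expect_error(run_cv(d$x, d$y, "svm", folds = 30),
               class = "wb_invalid_config")
})

test_that("stratified folds keep both classes when counts allow", {
  y <- factor(rep(c("HE", "PD"), c(12, 12)))
  x <- matrix(rnorm(48), 24)
  with_both <- TRUE
  for (seed in 1:5) {
    set.seed(seed)
    fold_id <- integer(24)
    for (lv in levels(y)) {
      idx <- which(y == lv)
      fold_id[idx] <- sample(rep_len(1:6, length(idx)))
    }
    for (f in 1:6)
      with_both <- with_both && nlevels(droplevels(y[fold_id == f])) == 2
  }
  expect_true(with_both)
  # and run_cv completes with every classifier on a small balanced cohort
  d <- make_xy(n = 20, sep = 3, seed = 5)
  for (cl in wb_classifiers()) {
    cv <- run_cv(d$x, d$y, cl, n_runs = 2, folds = 5, seed = 1)
    expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1), info = cl)
    expect_length(cv$accuracy, 2)
  }
})

test_that("a feature builder reproduces the fixed-matrix route", {
  d <- make_xy(n = 20, sep = 2, seed = 12)
  plain <- run_cv(d$x, d$y, "knn", n_runs = 3, folds = 5, seed = 2)
  built <- run_cv(labels = d$y, classifier = "knn", n_runs = 3, folds = 5,
                  seed = 2, builder = function(tr, te)
                    list(train = d$x[tr, , drop = FALSE],
                         test = d$x[te, , drop = FALSE]))
  expect_identical(plain$accuracy, built$accuracy)
  # and a builder may construct fold-scoped features (leak-free route):
  # standardisation parameters from the training subjects only
  seen_test_rows <- FALSE
  lf <- run_cv(labels = d$y, classifier = "knn", n_runs = 2, folds = 5,
               seed = 3, builder = function(tr, te) {
                 mu <- colMeans(d$x[tr, , drop = FALSE])
                 seen_test_rows <<- seen_test_rows || any(te %in% tr)
                 list(train = sweep(d$x[tr, , drop = FALSE], 2, mu),
                      test = sweep(d$x[te, , drop = FALSE], 2, mu))
               })
  expect_false(seen_test_rows)
  expect_length(lf$accuracy, 2)
})

test_that("AdaBoost stumps separate a threshold rule", {
  set.seed(6)
  y <- factor(rep(c("a", "b"), each = 20))
  x <- cbind(f1 = c(rnorm(20, -2), rnorm(20, 2)), f2 = rnorm(40))
  fit <- wristbow:::adaboost_fit(x, y, rounds = 10)
  pr <- wristbow:::adaboost_predict(fit, x)
  expect_equal(mean(pr$class == y), 1)
})

test_that("GA fitness trace is non-decreasing and respects generations = 0", {
  d <- make_xy(n = 24, p = 8, sep = 2, seed = 7)
  ga0 <- ga_select(d$x, d$y, ga_config(population_size = 6, generations = 0, parents_selected = 4),
                   classifiers = "svm", folds = 4, seed = 1)
  expect_equal(ga0$generation, 0)
  expect_length(ga0$trace, 1)
  ga1 <- ga_select(d$x, d$y, ga_config(population_size = 8, generations = 4, parents_selected = 6),
                   classifiers = "svm", folds = 4, seed = 2)
  expect_true(all(diff(ga1$trace) >= 0))
  expect_true(any(ga1$mask))
  expect_named(ga1$mask, colnames(d$x))
})

test_that("GA with identical copies and zero sparsity returns a valid mask", {
  set.seed(8)
  y <- factor(rep(c("a", "b"), 12))
  x <- matrix(rep(rnorm(24), 4), 24, 4,
              dimnames = list(NULL, paste0("c", 1:4)))
  ga <- ga_select(x, y, ga_config(population_size = 6, generations = 2,
                                  parents_selected = 4, sparsity_weight = 0),
                  classifiers = "knn", folds = 4, seed = 3)
  expect_true(any(ga$mask))
  expect_error(ga_select(x[, 1, drop = FALSE], y),
               class = "wb_invalid_config")
})

test_that("evaluate_feature_sets pairs runs across sets and validates ids", {
  d <- make_xy(n = 20, sep = 2, seed = 9)
  rownames(d$x) <- paste0("S", 1:20)
  sets <- list(one = d$x, two = d$x)
  res <- evaluate_feature_sets(sets, d$y, classifiers = c("svm", "knn"),
                               n_runs = 2, folds = 5, seed = 4)
  expect_identical(res$results$one$svm$accuracy, res$results$two$svm$accuracy)
  expect_equal(nrow(res$summary), 4)
  expect_true(all(res$summary$mean_accuracy >= 0 &
                    res$summary$mean_accuracy <= 1))
  tab <- format_results_table(res)
  expect_equal(dim(tab), c(2, 4))
  expect_match(tab$svm[1], "±")

  bad <- d$x; rownames(bad) <- paste0("X", 1:20)
  expect_error(evaluate_feature_sets(list(a = d$x, b = bad), d$y),
               class = "wb_invalid_config")
})
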