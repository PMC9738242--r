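# The six classifiers of the study: RBF-kernel SVM, naive Bayes, decision
# tree, random forest, k-nearest neighbours and AdaBoost.  Hyperparameters
# are unstated in the source protocol; the values pinned here are the
# field-standard defaults and are recorded in every result object.

#' Classifier identifiers
#'
#' @return Character vector of the six supported classifier ids: `"svm"`
#'   (RBF kernel), `"nb"`, `"dt"`, `"rf"`, `"knn"`, `"ab"`.
#' @export
wb_classifiers <- function() c("svm", "nb", "dt", "rf", "knn", "ab")

#' Pinned classifier hyperparameters
#'
#' @return Named list of the hyperparameters used by [run_cv()]:
#'   RBF SVM with the 1/p bandwidth heuristic and cost 1; KNN with k = 5
#'   on standardised features; random forest with 100 trees; AdaBoost.M1
#'   with 50 decision stumps; rpart and naive Bayes defaults.
#' @export
wb_hyperparameters <- function() {
  list(svm = list(kernel = "radial", cost = 1, gamma = "1/p"),
       nb = list(), dt = list(method = "class"),
       rf = list(ntree = 100), knn = list(k = 5, standardize = TRUE),
       ab = list(rounds = 50, learner = "decision stump"))
}

# Train on (xtr, ytr), predict classes and positive-class scores on xte.
# y is a 2-level factor; scores are for the second level.
fit_predict <- function(classifier, xtr, ytr, xte, seed = NULL) {
  lev <- levels(ytr)
  majority <- lev[which.max(tabulate(ytr))]
  keep <- apply(xtr, 2, function(v) sd(v) > 0)
  if (!any(keep))
    return(list(class = factor(rep(majority, nrow(xte)), levels = lev),
                score = rep(0.5, nrow(xte))))
  xtr <- xtr[, keep, drop = FALSE]
  xte <- xte[, keep, drop = FALSE]
  out <- switch(classifier,
    svm = {
      fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = 1, scale = TRUE)
      pr <- predict(fit, xte, decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      # decision values are oriented towards the first level of the pair name
      if (grepl(paste0("^", lev[2], "/"), colnames(attr(pr, "decision.values"))[1]))
        dv <- dv else dv <- -dv
      list(class = pr, score = dv)
    },
    nb = {
      fit <- e1071::naiveBayes(xtr, ytr)
      p <- predict(fit, xte, type = "raw")
      sc <- p[, lev[2]]
      cl <- factor(ifelse(sc > 0.5, lev[2], lev[1]), levels = lev)
      list(class = cl, score = sc)
    },
    dt = {
      df <- data.frame(.y = ytr, xtr, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      p <- predict(fit, data.frame(xte, check.names = FALSE), type = "prob")
      sc <- p[, lev[2]]
      list(class = factor(ifelse(sc > 0.5, lev[2], lev[1]), levels = lev),
           score = sc)
    },
    rf = {
      fit <- randomForest::randomForest(xtr, ytr, ntree = 100)
      p <- predict(fit, xte, type = "prob")
      sc <- p[, lev[2]]
      list(class = factor(ifelse(sc > 0.5, lev[2], lev[1]), levels = lev),
           score = sc)
    },
    knn = {
      mu <- colMeans(xtr); sdev <- apply(xtr, 2, sd); sdev[sdev == 0] <- 1
      ztr <- sweep(sweep(xtr, 2, mu), 2, sdev, "/")
      zte <- sweep(sweep(xte, 2, mu), 2, sdev, "/")
      pr <- class::knn(ztr, zte, ytr, k = 5, prob = TRUE)
      win <- attr(pr, "prob")
      sc <- ifelse(pr == lev[2], win, 1 - win)
      list(class = factor(pr, levels = lev), score = sc)
    },
    ab = {
      fit <- adaboost_fit(xtr, ytr, rounds = 50)
      adaboost_predict(fit, xte)
    },
    wb_stop("unknown classifier id: ", classifier,
            class = "wb_invalid_config"))
  bad <- is.na(out$class)
  if (any(bad)) {
    out$class[bad] <- majority
    out$score[is.na(out$score)] <- 0.5
  }
  out
}

# --- AdaBoost.M1 with decision stumps -------------------------------------
# Weighted exhaustive threshold search per feature; alpha = log((1-e)/e)/2.

stump_fit <- function(x, y01, w) {
  # y01 in {-1, +1}; returns best (feature, threshold, polarity, werr)
  best <- list(werr = Inf)
  pos <- sum(w[y01 > 0])
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    xs <- x[o, j]; ys <- y01[o]; ws <- w[o]
    # rule "+1 if x > thr": correct = sum_{<=i} w[y=-1] + sum_{>i} w[y=+1]
    cneg <- cumsum(ws * (ys < 0))
    cpos <- cumsum(ws * (ys > 0))
    corr <- c(pos, cneg + (pos - cpos))  # i = 0..n
    # splits only between distinct values
    okcut <- c(TRUE, xs[-length(xs)] < xs[-1] - 0)
    okcut <- c(okcut, TRUE)              # i = 0 and i = n always allowed
    corr[!okcut] <- NA
    err_pos <- 1 - corr                  # polarity +1
    err_neg <- corr                      # polarity -1 (flip)
    for (pol in c(1, -1)) {
      e <- if (pol > 0) err_pos else err_neg
      i <- which.min(e)
      if (length(i) && e[i] < best$werr) {
        thr <- if (i == 1) xs[1] - 1 else if (i > length(xs)) xs[length(xs)] + 1
               else (xs[i - 1] + xs[i]) / 2
        best <- list(werr = e[i], feature = j, threshold = thr, polarity = pol)
      }
    }
  }
  best
}

adaboost_fit <- function(x, y, rounds = 50) {
  lev <- levels(y)
  y01 <- ifelse(y == lev[2], 1, -1)
  n <- nrow(x)
  w <- rep(1 / n, n)
  stumps <- list()
  for (r in seq_len(rounds)) {
    st <- stump_fit(x, y01, w)
    e <- min(max(st$werr, 1e-10), 1 - 1e-10)
    st$alpha <- 0.5 * log((1 - e) / e)
    h <- st$polarity * ifelse(x[, st$feature] > st$threshold, 1, -1)
    w <- w * exp(-st$alpha * y01 * h)
    w <- w / sum(w)
    stumps[[r]] <- st
    if (st$werr <= 1e-10) break
  }
  list(stumps = stumps, levels = lev)
}

adaboost_predict <- function(fit, x) {
  margin <- rep(0, nrow(x))
  for (st in fit$stumps)
    margin <- margin + st$alpha * st$polarity *
      ifelse(x[, st$feature] > st$threshold, 1, -1)
  lev <- fit$levels
  list(class = factor(ifelse(margin > 0, lev[2], lev[1]), levels = lev),
       score = margin)
}

# Rank (Mann-Whitney) AUC of scores for the second factor level.
auc_rank <- function(score, y) {
  pos <- y == levels(y)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0 || anyNA(score)) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
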