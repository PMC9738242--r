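#' Genetic-algorithm settings for feature selection
#'
#' Defaults mirror the study protocol: a population of 40 random binary
#' masks evolved for 50 generations; each generation selects 20 parents
#' (the 10 fittest plus 10 random, which guards against premature
#' convergence), performs 4 uniform crossovers on random parent pairs,
#' and gives every parent a 14% chance of mutation (random bit flips).
#' Fitness combines accuracy and sparsity as
#' `mean CV accuracy - sparsity_weight * (selected / total)`; ties break
#' towards fewer features.  The best individual found so far is carried
#' forward (elitism), so the reported optimum is monotone over
#' generations.
#'
#' @param population_size,generations,parents_selected,
#'   crossovers_per_generation,mutation_prob,sparsity_weight see above.
#' @return A `wb_ga_config` list.
#' @export
ga_config <- function(population_size = 40, generations = 50,
                      parents_selected = 20, crossovers_per_generation = 4,
                      mutation_prob = 0.14, sparsity_weight = 0.05) {
  if (parents_selected > population_size)
    wb_stop("parents_selected must not exceed population_size",
            class = "wb_invalid_config")
  if (mutation_prob < 0 || mutation_prob > 1)
    wb_stop("mutation_prob must be in [0, 1]", class = "wb_invalid_config")
  structure(list(population_size = population_size, generations = generations,
                 parents_selected = parents_selected,
                 crossovers_per_generation = crossovers_per_generation,
                 mutation_prob = mutation_prob,
                 sparsity_weight = sparsity_weight),
            class = "wb_ga_config")
}

repair_mask <- function(mask) {
  if (!any(mask)) mask[sample.int(length(mask), 1)] <- TRUE
  mask
}

#' Genetic-algorithm feature selection
#'
#' Evolves binary feature-inclusion masks whose fitness is the mean
#' cross-validated accuracy over the given classifiers minus a sparsity
#' penalty (see [ga_config()]).  The CV fold seed is held fixed across
#' fitness evaluations within one selection run so that masks compete on
#' identical resampling noise; evaluated masks are cached.
#'
#' @param x feature matrix (>= 2 columns).
#' @param labels 2-level group factor.
#' @param ga a [ga_config()].
#' @param classifiers classifier ids entering the fitness average.
#' @param n_runs,folds CV settings used inside the fitness function (kept
#'   small by default: fitness is evaluated thousands of times).
#' @param seed RNG seed.
#' @return A `wb_feature_mask`: logical `mask` named by feature, the
#'   mask's `fitness`, the `generation` it appeared in, and `trace`, the
#'   best-so-far fitness per generation (non-decreasing).
#' @export
ga_select <- function(x, labels, ga = ga_config(),
                      classifiers = wb_classifiers(), n_runs = 1, folds = 5,
                      seed = 1) {
  x <- as.matrix(x)
  if (!ncol(x))
    wb_stop("empty feature table", class = "wb_invalid_config")
  if (ncol(x) < 2)
    wb_stop("feature selection needs at least 2 features",
            class = "wb_invalid_config")
  labels <- factor(labels)
  p <- ncol(x)
  cv_seed <- derive_seed(seed, 1)
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  fitness <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    accs <- vapply(classifiers, function(cl)
      mean(run_cv(x[, mask, drop = FALSE], labels, cl, n_runs = n_runs,
                  folds = folds, seed = cv_seed)$accuracy), numeric(1))
    val <- mean(accs) - ga$sparsity_weight * sum(mask) / p
    cache[[key]] <- val
    n_evals <<- n_evals + 1L
    val
  }
  better <- function(f1, n1, f2, n2) f1 > f2 || (f1 == f2 && n1 < n2)

  with_seed(seed, {
    pop <- lapply(seq_len(ga$population_size),
                  function(i) repair_mask(runif(p) < 0.5))
    best <- NULL
    trace <- numeric(0)
    for (gen in 0:ga$generations) {
      fits <- vapply(pop, fitness, numeric(1))
      ord <- order(-fits, vapply(pop, sum, numeric(1)))
      top <- pop[[ord[1]]]
      if (is.null(best) ||
          better(fits[ord[1]], sum(top), best$fitness, sum(best$mask)))
        best <- list(mask = top, fitness = fits[ord[1]], generation = gen)
      trace <- c(trace, best$fitness)
      if (gen == ga$generations) break
      n_fit <- ga$parents_selected %/% 2
      fittest <- ord[seq_len(min(n_fit, length(ord)))]
      rest <- setdiff(seq_along(pop), fittest)
      random <- if (length(rest)) sample(rest, min(ga$parents_selected - n_fit,
                                                   length(rest))) else integer(0)
      parents <- pop[c(fittest, random)]
      offspring <- lapply(seq_len(ga$crossovers_per_generation), function(i) {
        pair <- sample.int(length(parents), 2)
        pick <- runif(p) < 0.5
        repair_mask(ifelse(pick, parents[[pair[1]]], parents[[pair[2]]]))
      })
      mutated <- lapply(parents, function(m) {
        if (runif(1) < ga$mutation_prob) {
          flips <- runif(p) < 1 / p
          if (!any(flips)) flips[sample.int(p, 1)] <- TRUE
          m <- xor(m, flips)
        }
        repair_mask(m)
      })
      nxt <- c(list(best$mask), offspring, mutated)
      while (length(nxt) < ga$population_size)
        nxt <- c(nxt, list(repair_mask(runif(p) < 0.5)))
      pop <- nxt[seq_len(ga$population_size)]
    }
    structure(list(mask = stats::setNames(best$mask, colnames(x)),
                   fitness = best$fitness, generation = best$generation,
                   trace = trace, n_evaluations = n_evals, config = ga,
                   classifiers = classifiers, seed = seed),
              class = "wb_feature_mask")
  })
}

#' @export
print.wb_feature_mask <- function(x, ...) {
  cat(sprintf("<wb_feature_mask: %d/%d features, fitness %.4f (gen %d)>\n",
              sum(x$mask), length(x$mask), x$fitness, x$generation))
  invisible(x)
}
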