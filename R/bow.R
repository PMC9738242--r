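#' K-medoid clustering of descriptor vectors
#'
#' Partitioning Around Medoids (build + swap, via [cluster::pam()]) on
#' Euclidean distances, optionally after per-column standardisation.  The
#' ten SDS components mix units (g and z-score units), so standardisation
#' is the default; without it a single component dominates the metric.
#' The swap phase is a local search, so in addition to the deterministic
#' build start, `starts` seeded random initialisations are run and the
#' solution with the smallest total point-to-medoid distance is kept.
#'
#' @param points numeric matrix of descriptor vectors (rows).
#' @param k number of medoids; must not exceed the number of distinct
#'   rows.
#' @param standardize standardise columns before computing distances.
#' @param seed seed for the random starts.
#' @param starts number of additional random initialisations.
#' @return List with `medoid_idx` (row indices of the medoids),
#'   `medoids`, `cluster` (1-based assignments), `objective` (sum of
#'   point-to-medoid distances, the quantity PAM minimises) and `wcss`
#'   (sum of squared distances, used for elbow curves).  Distances are in
#'   the standardised space when `standardize = TRUE`.
#' @examples
#' pts <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 5), 10))
#' kmedoids(pts, 2)$cluster
#' @export
kmedoids <- function(points, k, standardize = TRUE, seed = 1, starts = 3) {
  points <- as.matrix(points)
  if (k < 1 || k > nrow(points))
    wb_stop("k must be in 1..nrow(points)", class = "wb_invalid_config")
  if (nrow(unique(points)) < k)
    wb_stop("k exceeds the number of distinct points",
            class = "wb_invalid_config")
  z <- if (standardize) standardize_cols(points) else
    list(x = points, center = rep(0, ncol(points)), scale = rep(1, ncol(points)))
  idx <- if (k == nrow(points)) seq_len(k) else
    pam_multistart(z$x, k, seed = seed, starts = starts)
  med <- z$x[idx, , drop = FALSE]
  nn <- .nearest_medoid_cpp(z$x, med)
  list(medoid_idx = idx, medoids = points[idx, , drop = FALSE],
       cluster = nn$cluster, objective = sum(sqrt(nn$d2)), wcss = nn$wcss,
       center = z$center, scale = z$scale)
}

# Build-start PAM plus `starts` random initialisations; returns the medoid
# row indices with the smallest total distance.
pam_multistart <- function(x, k, seed = 1, starts = 3) {
  objective <- function(idx)
    sum(sqrt(.nearest_medoid_cpp(x, x[idx, , drop = FALSE])$d2))
  fit <- cluster::pam(x, k, metric = "euclidean", pamonce = 5,
                      keep.diss = FALSE, keep.data = FALSE)
  best <- fit$id.med
  best_obj <- objective(best)
  if (starts > 0 && k < nrow(x)) {
    rnd <- with_seed(seed, tryCatch(
      cluster::pam(x, k, metric = "euclidean", medoids = "random",
                   nstart = starts, keep.diss = FALSE,
                   keep.data = FALSE)$id.med,
      error = function(e) NULL))
    if (!is.null(rnd)) {
      rnd_obj <- objective(rnd)
      if (rnd_obj < best_obj - 1e-12) best <- rnd
    }
  }
  best
}

standardize_cols <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  list(x = sweep(sweep(x, 2, mu), 2, sdev, "/"), center = mu, scale = sdev)
}

#' Automated elbow selection on a WCSS curve
#'
#' Returns the candidate `k` maximising the perpendicular distance to the
#' chord joining the curve's endpoints, after rescaling both axes to
#' \[0, 1\] so the choice is invariant to the units of WCSS.  Endpoints are
#' excluded (their distance is identically zero); ties resolve to the
#' smaller `k`, so an exactly linear curve yields the smallest interior
#' candidate.
#'
#' @param wcss_curve data frame with columns `k` and `wcss` (or a named
#'   numeric vector of WCSS values with `k` as names), at least 3
#'   candidates, non-increasing in `k`.
#' @return The selected `k`.
#' @examples
#' select_k_elbow(data.frame(k = c(4, 8, 20, 32),
#'                           wcss = c(90, 60, 10, 8)))
#' @export
select_k_elbow <- function(wcss_curve) {
  if (is.numeric(wcss_curve) && !is.null(names(wcss_curve)))
    wcss_curve <- data.frame(k = as.numeric(names(wcss_curve)),
                             wcss = as.numeric(wcss_curve))
  stopifnot(is.data.frame(wcss_curve), all(c("k", "wcss") %in% names(wcss_curve)))
  cv <- wcss_curve[order(wcss_curve$k), ]
  if (nrow(cv) < 3)
    wb_stop("elbow selection needs at least 3 candidates",
            class = "wb_invalid_config")
  if (any(diff(cv$wcss) > abs(cv$wcss[-nrow(cv)]) * 1e-9 + 1e-12))
    wb_stop("WCSS curve increases with k: clustering unstable",
            class = "wb_unstable_clustering")
  kr <- (cv$k - cv$k[1]) / (cv$k[nrow(cv)] - cv$k[1])
  wr <- if (cv$wcss[1] == cv$wcss[nrow(cv)]) rep(0, nrow(cv)) else
    (cv$wcss - cv$wcss[nrow(cv)]) / (cv$wcss[1] - cv$wcss[nrow(cv)])
  # distance of (kr, wr) to the chord from (0, 1) to (1, 0): |kr + wr - 1|/sqrt(2)
  d <- abs(kr + wr - 1) / sqrt(2)
  interior <- seq_len(nrow(cv))[-c(1, nrow(cv))]
  best <- interior[d[interior] >= max(d[interior]) - 1e-12]
  cv$k[min(best)]
}

#' Learn a per-window-size word vocabulary
#'
#' Pools the cohort's segment descriptors at one window size, clusters
#' them with PAM for each candidate `k`, evaluates the within-cluster sum
#' of squares of the full descriptor set against each candidate's
#' medoids, and picks `k` by [select_k_elbow()].  For large descriptor
#' sets a CLARA-style scheme is used: PAM runs on a seeded subsample
#' (`subsample` rows, `restarts` independent draws, best full-set WCSS
#' kept) and only the WCSS evaluation touches every descriptor.
#' Standardisation parameters are estimated from the vocabulary-building
#' set and stored for reuse at encoding time.
#'
#' @param desc pooled descriptor matrix (a `valid` column, if present, is
#'   dropped).
#' @param subjects optional integer/character subject id per row; at
#'   least 2 distinct subjects are required when supplied.
#' @param k_candidates candidate word counts (study set 4, 8, ..., 32).
#' @param seed RNG seed for subsampling.
#' @param subsample maximum rows handed to PAM per restart.
#' @param restarts number of subsample draws (1 when the data fit in one
#'   subsample).
#' @param window_s window size label stored in the model.
#' @return A `wb_vocabulary`: `k`, `medoids` (original units),
#'   `center`/`scale`, `wcss_curve`, `k_candidates`, `seed`, `window_s`.
#' @export
build_vocabulary <- function(desc, subjects = NULL,
                             k_candidates = c(4, 8, 12, 16, 20, 24, 28, 32),
                             seed = 1, subsample = 20000, restarts = 5,
                             window_s = NA_real_) {
  desc <- as.matrix(desc)
  if ("valid" %in% colnames(desc))
    desc <- desc[, setdiff(colnames(desc), "valid"), drop = FALSE]
  if (!is.null(subjects) && length(unique(subjects)) < 2)
    wb_stop("vocabulary needs descriptors from at least 2 subjects",
            class = "wb_invalid_config")
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (length(k_candidates) < 3)
    wb_stop("need at least 3 candidate k values", class = "wb_invalid_config")
  if (subsample < max(k_candidates))
    wb_stop("subsample smaller than the largest candidate k",
            class = "wb_invalid_config")
  n <- nrow(desc)
  if (n < max(k_candidates))
    wb_stop("fewer descriptors than the largest candidate k",
            class = "wb_invalid_config")
  z <- standardize_cols(desc)
  eff_restarts <- if (n <= subsample) 1L else as.integer(restarts)
  best <- lapply(k_candidates, function(k) NULL)
  names(best) <- as.character(k_candidates)
  pool <- integer(0)
  for (r in seq_len(eff_restarts)) {
    idx <- if (n <= subsample) seq_len(n) else
      with_seed(derive_seed(seed, r), sample.int(n, subsample))
    pool <- union(pool, idx)
    zs <- z$x[idx, , drop = FALSE]
    for (k in k_candidates) {
      fit_idx <- pam_multistart(zs, k, starts = 0)
      med_rows <- idx[fit_idx]
      wcss <- .nearest_medoid_cpp(z$x, z$x[med_rows, , drop = FALSE])$wcss
      key <- as.character(k)
      if (is.null(best[[key]]) || wcss < best[[key]]$wcss)
        best[[key]] <- list(wcss = wcss, med_rows = med_rows)
    }
  }
  # With subsampled PAM the full-set WCSS need not be monotone in k by
  # luck of the draw.  Repair violations by nested refinement: augment
  # the previous candidate's medoid set with farthest-point medoids from
  # the subsample pool -- adding a medoid can only lower the WCSS, so the
  # reported curve is non-increasing by construction.
  for (i in seq_along(k_candidates)[-1]) {
    prev <- best[[i - 1]]
    key <- as.character(k_candidates[i])
    if (best[[key]]$wcss > prev$wcss) {
      med <- prev$med_rows
      while (length(med) < k_candidates[i]) {
        nn <- .nearest_medoid_cpp(z$x, z$x[med, , drop = FALSE])
        free <- setdiff(pool, med)
        med <- c(med, free[which.max(nn$d2[free])])
      }
      wcss <- .nearest_medoid_cpp(z$x, z$x[med, , drop = FALSE])$wcss
      if (wcss < best[[key]]$wcss)
        best[[key]] <- list(wcss = wcss, med_rows = med)
    }
  }
  curve <- data.frame(k = k_candidates,
                      wcss = vapply(best, function(b) b$wcss, numeric(1)))
  k_star <- select_k_elbow(curve)
  med_rows <- best[[as.character(k_star)]]$med_rows
  structure(list(window_s = window_s, k = k_star,
                 medoids = desc[med_rows, , drop = FALSE],
                 center = z$center, scale = z$scale,
                 wcss_curve = curve, k_candidates = k_candidates,
                 seed = seed),
            class = "wb_vocabulary")
}

#' @export
print.wb_vocabulary <- function(x, ...) {
  cat(sprintf("<wb_vocabulary: window %s s, k = %d (candidates %s)>\n",
              format(x$window_s), x$k, paste(x$k_candidates, collapse = ",")))
  invisible(x)
}

#' @export
plot.wb_vocabulary <- function(x, ...) {
  plot(x$wcss_curve$k, x$wcss_curve$wcss, type = "b", xlab = "k",
       ylab = "WCSS", main = sprintf("Elbow curve (window %s s)",
                                     format(x$window_s)), ...)
  graphics::abline(v = x$k, lty = 2)
  invisible(x)
}

#' Encode a subject's segments as word counts
#'
#' Maps each segment descriptor to its nearest vocabulary medoid (in the
#' vocabulary's standardised space) and accumulates word counts.
#'
#' @param desc one subject's descriptor matrix at the vocabulary's window
#'   size (a `valid` column is dropped).
#' @param vocab a `wb_vocabulary`.
#' @return Integer count vector of length `vocab$k`.
#' @export
encode_document <- function(desc, vocab) {
  stopifnot(inherits(vocab, "wb_vocabulary"))
  desc <- as.matrix(desc)
  if ("valid" %in% colnames(desc))
    desc <- desc[, setdiff(colnames(desc), "valid"), drop = FALSE]
  if (!nrow(desc))
    wb_stop("no segments to encode", class = "wb_invalid_config")
  if (!all(is.finite(desc))) {
    bad <- which(!apply(desc, 1, function(r) all(is.finite(r))))[1]
    wb_stop("non-finite descriptor in segment ", bad,
            class = "wb_invalid_config")
  }
  zd <- sweep(sweep(desc, 2, vocab$center), 2, vocab$scale, "/")
  zm <- sweep(sweep(vocab$medoids, 2, vocab$center), 2, vocab$scale, "/")
  nn <- .nearest_medoid_cpp(zd, zm)
  tabulate(nn$cluster, nbins = vocab$k)
}

#' Term frequencies of a word-count document
#'
#' @param counts non-negative word counts with at least one word.
#' @return `counts / sum(counts)`; sums to 1 exactly.
#' @examples
#' term_frequencies(c(2, 1, 0)) # 2/3, 1/3, 0
#' @export
term_frequencies <- function(counts) {
  if (any(counts < 0))
    wb_stop("negative word count", class = "wb_invalid_config")
  total <- sum(counts)
  if (total < 1)
    wb_stop("document has no words", class = "wb_invalid_config")
  counts / total
}

#' Concatenate per-strategy term-frequency vectors
#'
#' @param tfs named list of per-window TF vectors; names are window sizes
#'   in seconds.  Input order is irrelevant: strategies are concatenated
#'   in ascending window order.
#' @param strategies the strategy set that must be present (defaults to
#'   the names of `tfs`).
#' @return Single numeric vector of length `sum(k)`.
#' @export
concatenate_strategies <- function(tfs, strategies = NULL) {
  if (is.null(strategies)) strategies <- names(tfs)
  strategies <- as.character(sort(as.numeric(strategies)))
  missing <- setdiff(strategies, names(tfs))
  if (length(missing))
    wb_stop("missing strategy: ", paste(missing, collapse = ", "),
            class = "wb_invalid_config")
  unlist(lapply(strategies, function(s) {
    v <- tfs[[s]]
    names(v) <- sprintf("w%ss_%02d", s, seq_along(v))
    v
  }))
}

#' Word-document (term-frequency) feature table for a cohort
#'
#' Builds one vocabulary per window size (unless supplied), encodes each
#' subject's segments as word counts, converts counts to term
#' frequencies, and concatenates the per-strategy TF vectors in ascending
#' window order.
#'
#' In the cohort-wide scope the vocabulary is learned from all subjects'
#' descriptors, as the original procedure does (test subjects leak into
#' the vocabulary).  Passing `train_subjects` restricts
#' vocabulary-building to those subjects (leak-free scope); all subjects
#' are still encoded.
#'
#' @param cd a [cohort_descriptors()] result.
#' @param k_candidates,seed,subsample,restarts passed to
#'   [build_vocabulary()].
#' @param vocabs optional pre-built list of vocabularies named by window.
#' @param train_subjects optional subject indices (rows of the roster)
#'   whose descriptors build the vocabularies.
#' @return Numeric matrix of TF features (rows = subjects, columns
#'   `w<window>s_<i>`), with the vocabularies attached as attribute
#'   `"vocabularies"`.
#' @export
word_features <- function(cd, k_candidates = c(4, 8, 12, 16, 20, 24, 28, 32),
                          seed = 1, subsample = 20000, restarts = 5,
                          vocabs = NULL, train_subjects = NULL) {
  stopifnot(inherits(cd, "wb_descriptors"))
  n <- nrow(cd$roster)
  wins <- names(cd$windows)
  if (is.null(vocabs)) {
    vocabs <- lapply(wins, function(w) {
      d <- cd$windows[[w]]$desc
      subj <- cd$windows[[w]]$subject
      rows <- if (is.null(train_subjects)) seq_len(nrow(d)) else
        which(subj %in% train_subjects)
      build_vocabulary(d[rows, , drop = FALSE], subjects = subj[rows],
                       k_candidates = k_candidates,
                       seed = derive_seed(seed, match(w, wins)),
                       subsample = subsample, restarts = restarts,
                       window_s = as.numeric(w))
    })
    names(vocabs) <- wins
  }
  rows <- lapply(seq_len(n), function(i) {
    tfs <- lapply(wins, function(w) {
      d <- cd$windows[[w]]
      term_frequencies(encode_document(d$desc[d$subject == i, , drop = FALSE],
                                       vocabs[[w]]))
    })
    names(tfs) <- wins
    concatenate_strategies(tfs, strategies = wins)
  })
  x <- do.call(rbind, rows)
  rownames(x) <- cd$roster$subject_id
  attr(x, "vocabularies") <- vocabs
  x
}

#' Serialise a vocabulary to JSON
#'
#' @param vocab a `wb_vocabulary`.
#' @param path output file.
#' @return `read_vocabulary_json()` returns the restored
#'   `wb_vocabulary`.
#' @export
write_vocabulary_json <- function(vocab, path) {
  stopifnot(inherits(vocab, "wb_vocabulary"))
  obj <- unclass(vocab)
  obj$medoids <- as.data.frame(obj$medoids)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary_json
#' @export
read_vocabulary_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$medoids <- as.matrix(obj$medoids)
  obj$center <- unlist(obj$center)
  obj$scale <- unlist(obj$scale)
  structure(obj, class = "wb_vocabulary")
}
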