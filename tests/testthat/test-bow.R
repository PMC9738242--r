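test_that("k-medoids recovers planted blobs and degenerate cases", {
  set.seed(1)
  pts <- rbind(matrix(rnorm(30, 0, 0.3), 10),
               matrix(rnorm(30, 6, 0.3), 10))
  km <- kmedoids(pts, 2, standardize = FALSE)
  lab <- rep(1:2, each = 10)
  agree <- max(mean(km$cluster == lab), mean(km$cluster == 3 - lab))
  expect_equal(agree, 1)

  km_n <- kmedoids(pts, nrow(pts))
  expect_equal(km_n$wcss, 0)
  expect_equal(sort(km_n$medoid_idx), 1:20)

  expect_error(kmedoids(pts, 25), class = "wb_invalid_config")
  dup <- pts[rep(1:2, 10), ]
  expect_error(kmedoids(dup, 3), class = "wb_invalid_config")
})

test_that("k-medoid objective matches exhaustive search on small instances", {
  set.seed(2)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    k <- min(sample(1:3, 1), n - 1)
    pts <- matrix(rnorm(n * 3), n)
    km <- kmedoids(pts, k, standardize = FALSE, seed = i)
    expect_equal(km$objective, exhaustive_kmedoid_objective(pts, k),
                 tolerance = 1e-9)
  }
})

test_that("elbow selection finds knees and applies the tie rule", {
  knee <- data.frame(k = c(4, 8, 12, 16, 20, 24, 28, 32),
                     wcss = c(500, 400, 300, 200, 100, 96, 92, 88))
  expect_equal(select_k_elbow(knee), 20)
  linear <- data.frame(k = c(4, 8, 12, 16), wcss = c(40, 30, 20, 10))
  expect_equal(select_k_elbow(linear), 8)   # ties -> smallest interior
  expect_error(select_k_elbow(data.frame(k = c(2, 4), wcss = c(2, 1))),
               class = "wb_invalid_config")
  expect_error(select_k_elbow(data.frame(k = c(2, 4, 8),
                                         wcss = c(3, 1, 2))),
               class = "wb_unstable_clustering")
  # hand-computed chord distances on a curved profile: after rescaling both
  # axes to [0,1], distances |kr + wr - 1|/sqrt(2) are maximal at k = 10
  curve <- data.frame(k = c(5, 10, 15, 20), wcss = c(100, 20, 10, 5))
  kr <- (curve$k - 5) / 15
  wr <- (curve$wcss - 5) / 95
  d <- abs(kr + wr - 1) / sqrt(2)
  expect_equal(curve$k[which.max(d[2:3]) + 1], 10)
  expect_equal(select_k_elbow(curve), 10)
})

test_that("vocabulary building recovers planted modes and validates input", {
  desc <- planted_mode_descriptors(seed = 10, modes = 4)
  v <- build_vocabulary(desc, k_candidates = c(2, 3, 4, 6, 8), seed = 1,
                        subsample = nrow(desc), window_s = 3)
  expect_s3_class(v, "wb_vocabulary")
  expect_equal(v$k, 4)
  expect_true(all(diff(v$wcss_curve$wcss) <= 1e-9))
  expect_true(v$k %in% v$k_candidates)

  expect_error(build_vocabulary(desc, subjects = rep(1, nrow(desc)),
                                k_candidates = c(2, 3, 4)),
               class = "wb_invalid_config")
  expect_error(build_vocabulary(desc, k_candidates = c(2, 3, 4),
                                subsample = 2),
               class = "wb_invalid_config")
})

test_that("vocabularies are deterministic given seed and subsample", {
  desc <- planted_mode_descriptors(seed = 3, modes = 3, per_mode = 120)
  v1 <- build_vocabulary(desc, k_candidates = c(2, 3, 4, 6), seed = 9,
                         subsample = 150, restarts = 2)
  v2 <- build_vocabulary(desc, k_candidates = c(2, 3, 4, 6), seed = 9,
                         subsample = 150, restarts = 2)
  expect_identical(v1$medoids, v2$medoids)
  expect_identical(v1$wcss_curve, v2$wcss_curve)
})

test_that("encoding assigns nearest medoids and is idempotent", {
  desc <- planted_mode_descriptors(seed = 4, modes = 4)
  v <- build_vocabulary(desc, k_candidates = c(2, 3, 4, 6, 8), seed = 2,
                        subsample = nrow(desc))
  counts <- encode_document(desc, v)
  expect_equal(sum(counts), nrow(desc))
  expect_identical(counts, encode_document(desc, v))
  # brute-force nearest-medoid oracle in the standardized space
  zd <- sweep(sweep(desc, 2, v$center), 2, v$scale, "/")
  zm <- sweep(sweep(v$medoids, 2, v$center), 2, v$scale, "/")
  assign <- apply(zd, 1, function(p)
    which.min(colSums((t(zm) - p)^2)))
  expect_equal(counts, tabulate(assign, nbins = v$k))
  # medoid rows themselves land on their own word
  expect_equal(encode_document(v$medoids, v), rep(1L, v$k))

  expect_error(encode_document(desc[0, ], v), class = "wb_invalid_config")
  bad <- desc[1:3, ]; bad[2, 5] <- NaN
  expect_error(encode_document(bad, v), "segment 2",
               class = "wb_invalid_config")
})

test_that("term frequencies are exact probability vectors", {
  expect_equal(term_frequencies(c(2, 1, 0)), c(2 / 3, 1 / 3, 0))
  expect_equal(term_frequencies(c(0, 5, 0)), c(0, 1, 0))
  expect_error(term_frequencies(c(0, 0)), class = "wb_invalid_config")
  set.seed(5)
  for (i in 1:50) {
    counts <- rpois(sample(2:40, 1), 3)
    if (sum(counts) == 0) counts[1] <- 1
    tf <- term_frequencies(counts)
    # exactness in rational terms: numerators recover the counts and sum
    # to the common denominator
    expect_identical(tf, counts / sum(counts))
    expect_identical(sum(counts) == Reduce(`+`, as.integer(counts)), TRUE)
    expect_equal(sum(tf), 1, tolerance = 1e-12)
    expect_true(all(tf >= 0))
  }
})

test_that("strategy concatenation is order-normalised and validated", {
  tfs <- list("900" = rep(1 / 16, 16), "3" = rep(1 / 22, 22),
              "10" = rep(1 / 22, 22), "300" = rep(1 / 20, 20),
              "60" = rep(1 / 20, 20))
  out <- concatenate_strategies(tfs)
  expect_length(out, 100)
  expect_match(names(out)[1], "^w3s_")
  expect_match(names(out)[100], "^w900s_")
  permuted <- concatenate_strategies(tfs[c(3, 1, 5, 2, 4)])
  expect_identical(out, permuted)
  single <- concatenate_strategies(list("60" = c(0.5, 0.5)))
  expect_equal(unname(single), c(0.5, 0.5))
  expect_error(concatenate_strategies(tfs[-1], strategies = names(tfs)),
               class = "wb_invalid_config")
})

test_that("word feature tables are probability blocks per strategy", {
  cfg <- tiny_config(seed = 21, n = 4, day_len_s = 120, windows = c(3, 10))
  cd <- cohort_descriptors(cfg)
  x <- word_features(cd, k_candidates = c(2, 3, 4, 6), seed = 1,
                     subsample = 400)
  expect_equal(rownames(x), cd$roster$subject_id)
  for (w in c(3, 10)) {
    block <- x[, grep(sprintf("^w%ds_", w), colnames(x)), drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, nrow(x)), tolerance = 1e-12)
  }
  vocabs <- attr(x, "vocabularies")
  expect_named(vocabs, c("3", "10"))
  expect_equal(ncol(x), sum(vapply(vocabs, `[[`, integer(1), "k")))
})

test_that("leak-free vocabularies depend only on training subjects", {
  cfg <- tiny_config(seed = 22, n = 4, day_len_s = 90, windows = 3)
  cd <- cohort_descriptors(cfg)
  hash_vocab <- function(v) digest_vocab(v)
  digest_vocab <- function(v)
    paste(format(v$medoids, digits = 12), collapse = "|")
  x1 <- word_features(cd, k_candidates = c(2, 3, 4), seed = 1,
                      train_subjects = 1:4)
  x2 <- word_features(cd, k_candidates = c(2, 3, 4), seed = 1,
                      train_subjects = 1:4)
  x3 <- word_features(cd, k_candidates = c(2, 3, 4), seed = 1,
                      train_subjects = 3:6)
  h <- function(x) digest_vocab(attr(x, "vocabularies")[["3"]])
  expect_identical(h(x1), h(x2))
  expect_false(identical(h(x1), h(x3)))
  # encoding covers all subjects in both scopes
  expect_equal(nrow(x1), 8)
})

test_that("vocabulary JSON serialisation round-trips", {
  desc <- planted_mode_descriptors(seed = 6, modes = 3, per_mode = 50)
  v <- build_vocabulary(desc, k_candidates = c(2, 3, 4), seed = 1,
                        subsample = nrow(desc), window_s = 60)
  f <- withr::local_tempfile(fileext = ".json")
  write_vocabulary_json(v, f)
  r <- read_vocabulary_json(f)
  expect_equal(r$k, v$k)
  expect_equal(unname(r$medoids), unname(v$medoids), tolerance = 1e-12)
  expect_equal(unname(r$center), unname(v$center), tolerance = 1e-12)
  expect_equal(encode_document(desc, r), encode_document(desc, v))
})
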