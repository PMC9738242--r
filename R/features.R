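#' Per-segment descriptor set
#'
#' Computes the ten-value subsequence descriptor set (SDS) for every
#' half-overlapping window of a session: mean per-sample vector magnitude
#' `vm` (g); normalised RMS `rmsr_ap/ml/ver` (RMS per axis divided by the
#' root of the summed squared RMS, so the squares sum to 1); movement
#' dispersion `disp_ap/ml/ver` (mean absolute pairwise difference of
#' within-segment z-scores over non-outlier samples, outliers being
#' samples with |z| > 2 on any axis); and acceleration range `ar_ap/ml/ver`
#' (per-axis max minus min, g).  Device axes x, y, z are labelled AP, ML,
#' Ver in that fixed order; since every descriptor is either symmetric in
#' the axes or normalised, the mapping is a labelling convention only.
#'
#' z-scores use the population (n-denominator) standard deviation within
#' the segment.  Degenerate cases yield 0 rather than NaN: a zero-variance
#' axis has dispersion 0, as does a segment with fewer than 2 non-outlier
#' samples.  A segment that is identically zero on all axes has no defined
#' normalised RMS and is flagged `valid = 0`; such segments are excluded
#' from per-subject averaging.
#'
#' @param session an `accel_session`.
#' @param window_s window length (s).
#' @return Numeric matrix with one row per segment and columns `vm`,
#'   `rmsr_ap`, `rmsr_ml`, `rmsr_ver`, `disp_ap`, `disp_ml`, `disp_ver`,
#'   `ar_ap`, `ar_ml`, `ar_ver`, `valid`.
#' @export
segment_descriptors <- function(session, window_s) {
  stopifnot(inherits(session, "accel_session"))
  spec <- window_spec(window_s, session$fs_hz)
  n_seg <- segment_count(session$duration_s, spec$window_s)
  if (n_seg < 1)
    wb_stop("subject ", session$subject_id, ": duration shorter than the ",
            window_s, " s window", class = "wb_empty_segmentation")
  .sds_descriptors_cpp(session$samples, spec$len, n_seg)
}

descriptor_names <- function() {
  c("vm", "rmsr_ap", "rmsr_ml", "rmsr_ver", "disp_ap", "disp_ml",
    "disp_ver", "ar_ap", "ar_ml", "ar_ver")
}

as_segment_matrix <- function(segment) {
  segment <- as.matrix(segment)
  if (!nrow(segment)) wb_stop("empty segment", class = "wb_invalid_config")
  if (ncol(segment) != 3)
    wb_stop("a segment must have three axis columns",
            class = "wb_invalid_config")
  storage.mode(segment) <- "double"
  segment
}

single_sds <- function(segment) {
  m <- as_segment_matrix(segment)
  drop(.sds_descriptors_cpp(m, nrow(m), 1L))
}

#' Single-segment descriptor operations
#'
#' Scalar versions of the descriptor computations in
#' [segment_descriptors()], operating on one segment (an m x 3 matrix).
#' `vector_magnitude()` is the mean over samples of
#' `sqrt(x^2 + y^2 + z^2)`; `rmsr()` returns the normalised RMS triple
#' (all-`NA` with a warning for an identically zero segment, whose
#' normalisation is undefined); `dispersion()` the per-axis dispersion
#' (requires at least 2 samples); `acceleration_range()` the per-axis
#' max - min.
#'
#' @param segment numeric m x 3 matrix (axes AP, ML, Ver).
#' @return `vector_magnitude()` a scalar; the others named length-3
#'   vectors.
#' @examples
#' seg <- cbind(ap = c(3, 3), ml = c(4, 4), ver = c(0, 0))
#' vector_magnitude(seg) # 5
#' @export
vector_magnitude <- function(segment) {
  unname(single_sds(segment)["vm"])
}

#' @rdname vector_magnitude
#' @export
rmsr <- function(segment) {
  d <- single_sds(segment)
  out <- d[c("rmsr_ap", "rmsr_ml", "rmsr_ver")]
  if (d["valid"] == 0) {
    warning("all-zero segment: normalised RMS undefined, returning NA")
    out[] <- NA_real_
  }
  out
}

#' @rdname vector_magnitude
#' @export
dispersion <- function(segment) {
  m <- as_segment_matrix(segment)
  if (nrow(m) < 2)
    wb_stop("dispersion needs at least 2 samples", class = "wb_invalid_config")
  single_sds(m)[c("disp_ap", "disp_ml", "disp_ver")]
}

#' @rdname vector_magnitude
#' @export
acceleration_range <- function(segment) {
  single_sds(segment)[c("ar_ap", "ar_ml", "ar_ver")]
}

#' Averaged statistical features for one subject
#'
#' The unweighted mean of each descriptor over all the subject's segments
#' at each window size (flagged-invalid segments excluded), concatenated
#' over window sizes in ascending order.
#'
#' @param session an `accel_session`.
#' @param windows window lengths (s).
#' @return Named numeric vector, names `<descriptor>_<window>s`.
#' @export
subject_statistical_features <- function(session, windows = c(3, 10, 60, 300, 900)) {
  windows <- sort(windows)
  out <- lapply(windows, function(w) {
    d <- segment_descriptors(session, w)
    keep <- d[, "valid"] > 0
    if (!any(keep))
      wb_stop("subject ", session$subject_id, ": no valid segments at ",
              w, " s", class = "wb_empty_segmentation")
    v <- colMeans(d[keep, descriptor_names(), drop = FALSE])
    names(v) <- paste0(descriptor_names(), "_", format(w, trim = TRUE), "s")
    v
  })
  unlist(out)
}

#' Pooled per-window descriptors for a cohort
#'
#' Computes [segment_descriptors()] for every subject at every window
#' size.  When given a configuration rather than a generated cohort,
#' sessions are generated one at a time and the raw signal is discarded
#' after its descriptors are computed, so paper-scale cohorts never hold
#' all raw samples in memory.
#'
#' @param x an `accel_cohort` or a [cohort_config()].
#' @param windows window lengths (s); defaults to the config's set.
#' @param days for a config, generate only the first `days` day units.
#' @return A `wb_descriptors`: per window, the pooled descriptor matrix
#'   and the subject index of each row; plus the cohort roster.
#' @export
cohort_descriptors <- function(x, windows = NULL, days = NULL) {
  if (inherits(x, "wb_cohort_config")) {
    config <- x
    roster <- cohort_roster(config)
    get_session <- function(i) {
      prof <- if (roster$group[i] == "HE") config$he else config$pd
      generate_subject(prof, days = days %||% config$days,
                       day_len_s = config$day_len_s, fs_hz = config$fs_hz,
                       seed = roster$seed[i], subject_id = roster$subject_id[i])
    }
  } else if (inherits(x, "accel_cohort")) {
    roster <- x$roster
    config <- x$config
    get_session <- function(i) x$sessions[[i]]
  } else wb_stop("x must be an accel_cohort or wb_cohort_config",
                 class = "wb_invalid_config")
  if (is.null(windows)) windows <- config$windows
  windows <- sort(windows)
  n <- nrow(roster)
  if (n < 1) wb_stop("empty cohort", class = "wb_invalid_config")
  acc <- lapply(windows, function(w) vector("list", n))
  names(acc) <- as.character(windows)
  for (i in seq_len(n)) {
    s <- get_session(i)
    for (w in as.character(windows))
      acc[[w]][[i]] <- segment_descriptors(s, as.numeric(w))
  }
  per_window <- lapply(acc, function(lst) {
    list(desc = do.call(rbind, lst),
         subject = rep(seq_len(n), vapply(lst, nrow, integer(1))))
  })
  structure(list(windows = per_window, roster = roster,
                 window_s = windows),
            class = "wb_descriptors")
}

#' @export
print.wb_descriptors <- function(x, ...) {
  counts <- vapply(x$windows, function(w) nrow(w$desc), integer(1))
  cat(sprintf("<wb_descriptors: %d subjects; segments per window: %s>\n",
              nrow(x$roster),
              paste(names(counts), "s:", counts, collapse = ", ")))
  invisible(x)
}

#' Statistical feature table for a cohort
#'
#' One row per subject; per window size, the mean of each descriptor over
#' that subject's valid segments.  Columns are `<descriptor>_<window>s`
#' in ascending window order -- 10 per window, 50 for the full study set.
#'
#' @param cd a [cohort_descriptors()] result.
#' @return Numeric matrix, rownames = subject ids.
#' @export
stat_features <- function(cd) {
  stopifnot(inherits(cd, "wb_descriptors"))
  n <- nrow(cd$roster)
  blocks <- lapply(names(cd$windows), function(w) {
    d <- cd$windows[[w]]$desc
    subj <- cd$windows[[w]]$subject
    keep <- d[, "valid"] > 0
    m <- vapply(seq_len(n), function(i) {
      rows <- keep & subj == i
      if (!any(rows))
        wb_stop("subject ", cd$roster$subject_id[i],
                ": no valid segments at ", w, " s",
                class = "wb_empty_segmentation")
      colMeans(d[rows, descriptor_names(), drop = FALSE])
    }, numeric(10))
    m <- t(m)
    colnames(m) <- paste0(descriptor_names(), "_", w, "s")
    m
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- cd$roster$subject_id
  out
}
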