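#' Windowing specification
#'
#' A windowing strategy: fixed window length `window_s` seconds with 50%
#' overlap (step `window_s / 2`).  `window_s * fs_hz` must be a whole
#' number of samples so that window boundaries fall on samples.
#'
#' @param window_s window length (s); the study set is
#'   \{3, 10, 60, 300, 900\}.
#' @param fs_hz sampling rate (Hz).
#' @return A `wb_window_spec` list with `window_s`, `overlap_s`, `fs_hz`
#'   and the window length in samples `len`.
#' @examples
#' window_spec(3, 32)
#' @export
window_spec <- function(window_s, fs_hz) {
  if (window_s <= 0 || fs_hz <= 0)
    wb_stop("window_s and fs_hz must be positive", class = "wb_invalid_config")
  len <- window_s * fs_hz
  if (abs(len - round(len)) > 1e-8)
    wb_stop("window_s x fs_hz must be an integer number of samples",
            class = "wb_invalid_config")
  structure(list(window_s = window_s, overlap_s = window_s / 2,
                 fs_hz = fs_hz, len = as.integer(round(len))),
            class = "wb_window_spec")
}

#' Number of half-overlapping segments in a recording
#'
#' With 50% overlap, a duration of `t` seconds holds
#' `floor(2 * t / window_s) - 1` complete windows; any trailing partial
#' window is dropped.
#'
#' @param duration_s recording duration(s) in seconds (vectorised).
#' @param window_s window length (s).
#' @return Integer segment count(s); 0 when `duration_s < window_s`.
#' @examples
#' segment_count(30, 3)       # 19
#' segment_count(604800, 900) # 1343
#' @export
segment_count <- function(duration_s, window_s) {
  if (any(duration_s < 0) || window_s <= 0)
    wb_stop("durations must be non-negative and window_s positive",
            class = "wb_invalid_config")
  pmax(0L, as.integer(floor(2 * duration_s / window_s + 1e-9) - 1))
}

#' Total segment count over a cohort
#'
#' @param durations per-subject recording durations (s).
#' @param window_s window length (s).
#' @return Sum of [segment_count()] over subjects; 0 for an empty list.
#' @examples
#' cohort_segment_count(c(30, 30), 3) # 38
#' @export
cohort_segment_count <- function(durations, window_s) {
  if (!length(durations)) return(0L)
  if (any(durations <= 0))
    wb_stop("durations must be positive", class = "wb_invalid_config")
  sum(segment_count(durations, window_s))
}

# 0-based start indices (samples) of the half-open blocks
# [start, start + len); consecutive segments advance by len/2.
segment_starts <- function(n_seg, len) {
  if (n_seg < 1) return(integer(0))
  as.integer(floor((seq_len(n_seg) - 1) * len / 2))
}

#' Segment a session into half-overlapping windows
#'
#' @param session an `accel_session`.
#' @param spec a [window_spec()] (its `fs_hz` must match the session), or
#'   a window length in seconds.
#' @return A data frame with one row per segment: `subject_id`,
#'   `window_s`, `start_index` (0-based samples; the block is the
#'   half-open range `[start_index, start_index + len)`).
#' @export
segment_session <- function(session, spec) {
  stopifnot(inherits(session, "accel_session"))
  if (!inherits(spec, "wb_window_spec"))
    spec <- window_spec(spec, session$fs_hz)
  if (abs(spec$fs_hz - session$fs_hz) > 1e-9)
    wb_stop("window spec rate does not match session rate",
            class = "wb_invalid_config")
  n_seg <- segment_count(session$duration_s, spec$window_s)
  if (n_seg < 1)
    wb_stop("subject ", session$subject_id, ": duration ", session$duration_s,
            " s is shorter than the ", spec$window_s, " s window",
            class = "wb_empty_segmentation")
  data.frame(subject_id = session$subject_id, window_s = spec$window_s,
             start_index = segment_starts(n_seg, spec$len),
             stringsAsFactors = FALSE)
}

#' Extract one segment's sample block
#'
#' @param session an `accel_session`.
#' @param start_index 0-based start sample.
#' @param len block length in samples.
#' @return `len` x 3 matrix of samples.
#' @export
segment_block <- function(session, start_index, len) {
  if (start_index < 0 || start_index + len > nrow(session$samples))
    wb_stop("segment outside recording", class = "wb_invalid_config")
  session$samples[start_index + seq_len(len), , drop = FALSE]
}
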