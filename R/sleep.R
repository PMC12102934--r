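#' Sleep-detection parameters
#'
#' The detector binarizes epochs at a low-activity threshold and then flips
#' runs shorter than a minimum segment length to the opposite state, so that
#' brief stirrings inside a sleep bout or brief stillness during the day do
#' not fragment the state sequence. Bouts longer than `max_sleep_len` epochs
#' are treated as device malfunction and invalidated downstream.
#'
#' @param low_activity_threshold Counts/epoch at or below which an epoch is
#'   provisionally "rest" (default 10).
#' @param min_segment_len Minimum run length in epochs; shorter interior runs
#'   are flipped (default 30).
#' @param max_sleep_len Maximum valid sleep bout in epochs (default 900,
#'   i.e. 15 h at 1-min epochs).
#' @return A `sleep_params` list.
#' @export
sleep_params <- function(low_activity_threshold = 10,
                         min_segment_len = 30L,
                         max_sleep_len = 900L) {
  if (low_activity_threshold < 0) abort("low_activity_threshold must be >= 0")
  if (min_segment_len <= 0 || max_sleep_len <= 0) abort("segment lengths must be positive")
  if (min_segment_len >= max_sleep_len) abort("min_segment_len must be < max_sleep_len")
  structure(list(low_activity_threshold = low_activity_threshold,
                 min_segment_len = as.integer(min_segment_len),
                 max_sleep_len = as.integer(max_sleep_len)),
            class = "sleep_params")
}

# Flip interior runs shorter than min_len to the opposite state until no such
# run remains. Shortest run first, ties to the earlier run; runs touching the
# record boundaries are exempt (their true length is unknown). Operates on a
# logical vector, returns the stabilized logical vector.
flip_short_runs <- function(state, min_len) {
  r <- rle(state)
  len <- r$lengths
  val <- r$values
  repeat {
    k <- length(len)
    if (k <= 2) break
    interior <- 2:(k - 1)
    short <- interior[len[interior] < min_len]
    if (length(short) == 0) break
    pick <- short[which.min(len[short])]
    # flipping an interior run merges it with both (opposite-state) neighbors
    merged <- len[pick - 1] + len[pick] + len[pick + 1]
    keep_lo <- if (pick > 2) seq_len(pick - 2) else integer()
    keep_hi <- if (pick + 2 <= k) (pick + 2):k else integer()
    len <- c(len[keep_lo], merged, len[keep_hi])
    val <- c(val[keep_lo], val[pick - 1], val[keep_hi])
  }
  inverse.rle(structure(list(lengths = len, values = val), class = "rle"))
}

#' Detect sleep intervals from an epoch series
#'
#' Epochs at or below the low-activity threshold are marked as rest; interior
#' runs (rest or wake) shorter than `min_segment_len` are iteratively flipped
#' to the opposite state, shortest first, until a fixed point; maximal rest
#' runs are returned as sleep intervals. One interval may span midnight;
#' `night_id` numbers intervals, not calendar days.
#'
#' @param series An [epoch_series()] for one subject.
#' @param params A [sleep_params()].
#' @return A tibble with columns `subject_id`, `night_id`, `start_epoch`,
#'   `end_epoch` (half-open `[start, end)`, 1-based start) and `duration_min`.
#' @export
detect_sleep <- function(series, params = sleep_params()) {
  stopifnot(nrow(series) > 0)
  rest <- series$count <= params$low_activity_threshold
  rest <- flip_short_runs(rest, params$min_segment_len)
  r <- runs_of(rest)
  r <- filter(r, .data$value)
  mins_per_epoch <- epoch_len_s(series) / 60
  tibble::tibble(
    subject_id = series$subject_id[1],
    night_id = seq_len(nrow(r)),
    start_epoch = r$start,
    end_epoch = r$start + r$length,
    duration_min = r$length * mins_per_epoch
  )
}

#' Remove invalid (over-long) sleep intervals
#'
#' Sleep bouts longer than `max_sleep_len` epochs (default 15 h) are taken to
#' be device malfunction and removed; all other intervals pass unchanged.
#'
#' @param intervals Output of [detect_sleep()], sorted by start.
#' @param params A [sleep_params()].
#' @return The retained intervals, `night_id` renumbered.
#' @export
filter_valid_sleep <- function(intervals, params = sleep_params()) {
  out <- filter(intervals, .data$end_epoch - .data$start_epoch <= params$max_sleep_len)
  mutate(out, night_id = dplyr::row_number())
}

#' Mean nightly sleep time
#'
#' @param intervals Valid sleep intervals for one subject.
#' @return Mean interval duration in minutes (`slp_tm`), or `NA` if there are
#'   no intervals (propagated as a missing feature).
#' @export
sleep_time <- function(intervals) {
  if (nrow(intervals) == 0) return(NA_real_)
  mean(intervals$duration_min)
}

#' Extract per-night activity slices
#'
#' @param series The subject's [epoch_series()].
#' @param intervals Valid sleep intervals from [filter_valid_sleep()].
#' @return A list of `night_activity` lists (`night_id`, `counts`), in
#'   chronological order.
#' @export
night_slices <- function(series, intervals) {
  n <- nrow(series)
  purrr::pmap(
    list(intervals$night_id, intervals$start_epoch, intervals$end_epoch),
    function(id, s, e) {
      if (s < 1 || e > n + 1 || e <= s) abort("interval out of range")
      list(night_id = id, counts = series$count[s:(e - 1)])
    }
  )
}
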