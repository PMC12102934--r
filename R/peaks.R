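#' Extract nocturnal movement peaks from one night
#'
#' A peak is a maximal run of positive counts inside a sleep bout; zero
#' epochs separate peaks. Amplitude is the maximum count within the run by
#' default (`amplitude = "mean"` uses the run mean instead).
#'
#' @param night Numeric counts of one night, or a `night_activity` list.
#' @param amplitude `"max"` (default) or `"mean"` within the run.
#' @return A tibble with one row per peak: `start` (1-based epoch index
#'   within the night), `length` (epochs) and `amplitude`.
#' @export
extract_peaks <- function(night, amplitude = c("max", "mean")) {
  amplitude <- match.arg(amplitude)
  counts <- if (is.list(night)) night$counts else night
  r <- runs_of(counts > 0)
  r <- filter(r, .data$value)
  if (nrow(r) == 0) {
    return(tibble::tibble(start = integer(), length = integer(), amplitude = numeric()))
  }
  amp <- purrr::map2_dbl(r$start, r$length, function(s, l) {
    seg <- counts[s:(s + l - 1)]
    if (amplitude == "max") max(seg) else mean(seg)
  })
  tibble::tibble(start = r$start, length = r$length, amplitude = amp)
}

#' Split peaks into small and large classes
#'
#' `median` mode sends peaks with amplitude at or below the night median of
#' amplitudes to the small class and the rest to the large class (ties go to
#' small, so equal-amplitude nights are all small). `quartile` mode keeps
#' only the tails: amplitude at or below Q1 is small, at or above Q3 is
#' large, and mid-range peaks belong to neither class. Quartiles use linear
#' interpolation (type 7).
#'
#' @param peaks Tibble from [extract_peaks()].
#' @param mode `"median"` or `"quartile"`.
#' @return A list with tibbles `small` and `large`.
#' @export
split_peaks <- function(peaks, mode = c("median", "quartile")) {
  mode <- match.arg(mode)
  if (nrow(peaks) == 0) return(list(small = peaks, large = peaks))
  a <- peaks$amplitude
  if (mode == "median") {
    m <- median(a)
    list(small = peaks[a <= m, ], large = peaks[a > m, ])
  } else {
    q <- quantile(a, c(0.25, 0.75), type = 7, names = FALSE)
    list(small = peaks[a <= q[1], ], large = peaks[a >= q[2], ])
  }
}

#' Per-night peak metric vectors
#'
#' For an ordered set of peaks (typically one class within one night),
#' returns the amplitude (`a`) and length (`l`) vectors, the gaps (`d`)
#' between consecutive peaks of the set measured end-to-start in epochs, and
#' the number of close pairs (`cls`): consecutive pairs whose gap is at most
#' `close_gap_max`. Gaps are computed within the given set, ignoring peaks of
#' other classes that may interleave in the night.
#'
#' @param peaks Tibble of peaks sorted by `start`.
#' @param close_gap_max Largest gap (epochs) still counted as "close"
#'   (default 2).
#' @return A list with numeric vectors `a`, `l`, `d` and scalar `cls`.
#' @export
peak_metrics <- function(peaks, close_gap_max = 2L) {
  if (nrow(peaks) < 2) {
    return(list(a = peaks$amplitude, l = as.numeric(peaks$length),
                d = numeric(), cls = 0L))
  }
  ends <- peaks$start + peaks$length
  gaps <- peaks$start[-1] - ends[-nrow(peaks)]
  list(a = peaks$amplitude, l = as.numeric(peaks$length),
       d = as.numeric(gaps), cls = sum(gaps <= close_gap_max))
}

# The deterministic feature-name grammar: <category><metric>_<func>.
peak_feature_names <- function() {
  cats <- c("p_", "sp_", "lp_", "sp_q_", "lp_q_")
  funcs <- c("avg", "std", "max", "min", "med")
  base <- as.character(outer(
    cats,
    as.character(outer(c("a", "l", "d"), funcs, paste, sep = "_")),
    paste0
  ))
  counts <- c(paste0(cats, "nbr"), paste0(cats, "cls_nbr"))
  edges <- as.character(outer(c("p_first_", "p_last_"),
                              as.character(outer(c("a", "t"), c("avg", "std"),
                                                 paste, sep = "_")),
                              paste0))
  sort(c(base, counts, edges))
}

# Per-night feature values as a named numeric vector (NA = undefined that
# night; those nights are skipped when averaging across nights).
night_peak_values <- function(counts, close_gap_max, amplitude) {
  peaks <- extract_peaks(counts, amplitude = amplitude)
  med_split <- split_peaks(peaks, "median")
  q_split <- split_peaks(peaks, "quartile")
  sets <- list(p_ = peaks, sp_ = med_split$small, lp_ = med_split$large,
               sp_q_ = q_split$small, lp_q_ = q_split$large)
  funcs <- list(avg = mean, std = sd_pop, max = max, min = min, med = median)
  out <- c()
  for (cat in names(sets)) {
    m <- peak_metrics(sets[[cat]], close_gap_max = close_gap_max)
    for (metric in c("a", "l", "d")) {
      v <- m[[metric]]
      for (fn in names(funcs)) {
        out[paste0(cat, metric, "_", fn)] <-
          if (length(v)) funcs[[fn]](v) else NA_real_
      }
    }
    out[paste0(cat, "nbr")] <- nrow(sets[[cat]])
    out[paste0(cat, "cls_nbr")] <- m$cls
  }
  if (nrow(peaks)) {
    first <- peaks[1, ]
    last <- peaks[nrow(peaks), ]
    edge <- c(p_first_a = first$amplitude, p_first_t = as.numeric(first$start),
              p_last_a = last$amplitude, p_last_t = as.numeric(last$start))
  } else {
    edge <- c(p_first_a = NA_real_, p_first_t = NA_real_,
              p_last_a = NA_real_, p_last_t = NA_real_)
  }
  list(night = out, edge = edge)
}

#' Aggregate per-night peak features for one subject
#'
#' Every feature of the `<category><metric>_<func>` grammar is evaluated per
#' night and then averaged across the subject's valid nights; nights on which
#' a feature is undefined (e.g. no large peaks) are skipped for that feature.
#' First/last-peak amplitude (`_a`) and within-night start offset (`_t`) are
#' per-night scalars summarized by mean and SD across nights. A feature
#' undefined on all nights is returned as `NA`.
#'
#' @param nights List of nights from [night_slices()] (or numeric vectors).
#' @param close_gap_max Passed to [peak_metrics()].
#' @param amplitude Passed to [extract_peaks()].
#' @return A one-row tibble whose columns are [peak_feature_names()].
#' @export
peak_features <- function(nights, close_gap_max = 2L, amplitude = "max") {
  stopifnot(length(nights) >= 1)
  per_night <- purrr::map(nights, function(n) {
    counts <- if (is.list(n)) n$counts else n
    night_peak_values(counts, close_gap_max, amplitude)
  })
  night_mat <- do.call(rbind, purrr::map(per_night, "night"))
  agg <- apply(night_mat, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col)) mean(col) else NA_real_
  })
  edge_mat <- do.call(rbind, purrr::map(per_night, "edge"))
  edge <- c()
  for (nm in colnames(edge_mat)) {
    col <- edge_mat[, nm]
    col <- col[!is.na(col)]
    edge[paste0(nm, "_avg")] <- if (length(col)) mean(col) else NA_real_
    edge[paste0(nm, "_std")] <- if (length(col)) sd_pop(col) else NA_real_
  }
  all_vals <- c(agg, edge)[peak_feature_names()]
  tibble::as_tibble(as.list(all_vals))
}
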