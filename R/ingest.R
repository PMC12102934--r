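#' Band-pass filter specification
#'
#' Describes the Butterworth band-pass applied to raw acceleration before
#' epoching. The default 0.25-2.5 Hz band isolates gross voluntary movement
#' from both drift and high-frequency noise at a 10 Hz sampling rate.
#'
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz`.
#' @param order Butterworth design order (default 4); applied forward and
#'   backward (zero phase), so the effective order is doubled.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_hz = 0.25, high_hz = 2.5, order = 4L) {
  if (!(low_hz > 0 && high_hz > low_hz)) abort("need 0 < low_hz < high_hz")
  if (order < 1 || order != round(order)) abort("order must be a positive integer")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order)),
            class = "filter_spec")
}

#' Build a raw triaxial acceleration series
#'
#' @param x,y,z Acceleration per axis in g, equal lengths, uniformly sampled.
#' @param sampling_rate_hz Sampling rate in Hz (default 10).
#' @return A tibble of class `raw_triaxial` with columns `t_s,x_g,y_g,z_g`.
#' @export
raw_triaxial <- function(x, y, z, sampling_rate_hz = 10) {
  if (length(x) != length(y) || length(y) != length(z)) {
    abort("x, y, z must have equal length")
  }
  if (sampling_rate_hz <= 0) abort("sampling_rate_hz must be positive")
  out <- tibble::tibble(
    t_s = (seq_along(x) - 1) / sampling_rate_hz,
    x_g = as.numeric(x), y_g = as.numeric(y), z_g = as.numeric(z)
  )
  attr(out, "sampling_rate_hz") <- sampling_rate_hz
  class(out) <- c("raw_triaxial", class(out))
  out
}

#' Read a raw triaxial CSV (`t_s,x_g,y_g,z_g`)
#'
#' @param path Path to the CSV.
#' @param sampling_rate_hz Sampling rate; if `NULL`, inferred from the median
#'   timestamp increment.
#' @return A [raw_triaxial()] tibble.
#' @export
read_raw_csv <- function(path, sampling_rate_hz = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- read.csv(path)
  need <- c("t_s", "x_g", "y_g", "z_g")
  if (!all(need %in% names(df))) {
    abort("raw CSV must have columns t_s,x_g,y_g,z_g")
  }
  if (is.null(sampling_rate_hz)) {
    dt <- median(diff(df$t_s))
    if (!is.finite(dt) || dt <= 0) abort("cannot infer sampling rate from t_s")
    sampling_rate_hz <- 1 / dt
  }
  raw_triaxial(df$x_g, df$y_g, df$z_g, sampling_rate_hz = sampling_rate_hz)
}

# Zero-phase Butterworth band-pass of one channel.
bandpass_channel <- function(v, band, fs) {
  bf <- signal::butter(band$order, c(band$low_hz, band$high_hz) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, v))
}

#' Epoch raw acceleration with the PIM counting scheme
#'
#' Emulates proportional-integration-mode counting for a wrist device: each
#' axis is band-pass filtered, the three axes are combined into a per-sample
#' Euclidean magnitude, the maximum magnitude within each second is taken,
#' and the 60 per-second maxima of each minute are summed into one epoch
#' count. Counts are continuous (sums of filtered magnitudes), not integers.
#'
#' @param raw A [raw_triaxial()] series covering at least one full epoch.
#' @param band A [filter_spec()], or `NULL` to bypass filtering.
#' @param subject_id,start_time Metadata for the returned series.
#' @param filter_first If `TRUE` (default) each axis is filtered before the
#'   magnitude is formed; if `FALSE` the magnitude is filtered instead and
#'   its absolute value is used, since band-passing removes the DC level.
#' @return An [epoch_series()] of `floor(duration / 60 s)` epochs.
#' @export
pim_from_raw <- function(raw, band = filter_spec(),
                         subject_id = "S1",
                         start_time = as.POSIXct("2020-01-01 00:00:00", tz = "UTC"),
                         filter_first = TRUE) {
  fs <- attr(raw, "sampling_rate_hz") %||% 10
  if (!is.null(band) && fs <= 2 * band$high_hz) {
    abort("sampling rate must exceed twice the band's upper edge")
  }
  n <- nrow(raw)
  if (n < 60 * fs) abort("raw series shorter than one full epoch (60 s)")
  if (is.null(band)) {
    mag <- sqrt(raw$x_g^2 + raw$y_g^2 + raw$z_g^2)
  } else if (filter_first) {
    fx <- bandpass_channel(raw$x_g, band, fs)
    fy <- bandpass_channel(raw$y_g, band, fs)
    fz <- bandpass_channel(raw$z_g, band, fs)
    mag <- sqrt(fx^2 + fy^2 + fz^2)
  } else {
    mag <- abs(bandpass_channel(sqrt(raw$x_g^2 + raw$y_g^2 + raw$z_g^2), band, fs))
  }
  sps <- fs            # samples per second
  n_sec <- floor(n / sps)
  sec_idx <- rep(seq_len(n_sec), each = sps)
  sec_max <- vapply(split(mag[seq_len(n_sec * sps)], sec_idx), max, numeric(1))
  n_min <- floor(n_sec / 60)
  if (n_min < 1) abort("raw series shorter than one full epoch (60 s)")
  min_idx <- rep(seq_len(n_min), each = 60)
  counts <- vapply(split(sec_max[seq_len(n_min * 60)], min_idx), sum, numeric(1))
  # filtering ringing can leave tiny negative magnitudes in the abs() branch
  counts <- pmax(counts, 0)
  epoch_series(unname(counts), subject_id = subject_id, start_time = start_time)
}

#' Drop whole days with entirely missing signal
#'
#' Days whose counts are all zero typically mean the device was off or off
#' the wrist; they are removed as whole days. Partial days are never removed
#' here (no partial-day exclusion), and the operation is idempotent.
#'
#' @param series An [epoch_series()] of whole days (see [trim_partial_days()]).
#' @return The series with all-zero days removed and days renumbered.
#' @export
drop_missing_days <- function(series) {
  keep <- series %>%
    group_by(.data$day) %>%
    summarise(alive = any(.data$count > 0), .groups = "drop") %>%
    filter(.data$alive) %>%
    pull(.data$day)
  if (length(keep) == 0) abort("no valid days")
  rebuild_series(series, filter(series, .data$day %in% keep))
}
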