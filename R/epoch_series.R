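#' Build an epoch-count series
#'
#' The universal carrier between pipeline stages: one subject's activity
#' counts at a fixed epoch length (1 minute by default), laid out as a tibble
#' with one row per epoch. Days are delimited midnight-to-midnight on the
#' local clock, so the day index of an epoch is derived from `start_time`.
#'
#' @param counts Numeric vector of non-negative activity counts.
#' @param subject_id Subject identifier.
#' @param start_time `POSIXct` timestamp of the first epoch. Defaults to a
#'   midnight, so the series starts on a day boundary.
#' @param epoch_len_s Epoch length in seconds (default 60).
#' @return A tibble of class `epoch_series` with columns `subject_id`,
#'   `epoch` (1-based index), `day` (midnight-to-midnight day index) and
#'   `count`, plus `start_time` and `epoch_len_s` attributes.
#' @export
#' @examples
#' es <- epoch_series(rpois(1440, 50), subject_id = "S1")
#' dplyr::count(es, day)
epoch_series <- function(counts,
                         subject_id = "S1",
                         start_time = as.POSIXct("2020-01-01 00:00:00", tz = "UTC"),
                         epoch_len_s = 60L) {
  counts <- as.numeric(counts)
  if (length(counts) == 0) abort("no epochs")
  if (anyNA(counts) || any(counts < 0)) {
    abort("counts must be non-negative and non-missing")
  }
  if (length(epoch_len_s) != 1 || epoch_len_s <= 0 || epoch_len_s != round(epoch_len_s)) {
    abort("epoch_len_s must be a positive integer")
  }
  epoch_len_s <- as.integer(epoch_len_s)
  # seconds into the local day of the first epoch
  midnight <- as.POSIXct(format(start_time, "%Y-%m-%d"), tz = attr(start_time, "tzone") %||% "UTC")
  offset_s <- as.numeric(difftime(start_time, midnight, units = "secs"))
  idx <- seq_along(counts) - 1L
  day <- as.integer((offset_s + idx * epoch_len_s) %/% 86400) + 1L
  out <- tibble::tibble(
    subject_id = as.character(subject_id),
    epoch = seq_along(counts),
    day = day,
    count = counts
  )
  attr(out, "start_time") <- start_time
  attr(out, "epoch_len_s") <- epoch_len_s
  class(out) <- c("epoch_series", class(out))
  out
}

epoch_len_s <- function(series) attr(series, "epoch_len_s") %||% 60L

epochs_per_day <- function(series) as.integer(86400 / epoch_len_s(series))

#' Trim leading and trailing partial days
#'
#' Keeps only epochs belonging to complete midnight-to-midnight days, so that
#' window-based metrics (M10/L5) are comparable across subjects. Day indices
#' are renumbered from 1.
#'
#' @param series An [epoch_series()].
#' @return An `epoch_series` containing only whole days.
#' @export
trim_partial_days <- function(series) {
  ppd <- epochs_per_day(series)
  full <- series %>%
    group_by(.data$day) %>%
    filter(n() == ppd) %>%
    ungroup()
  if (nrow(full) == 0) abort("no whole days after trimming")
  rebuild_series(series, full)
}

# Re-sequence epochs/days after row subsetting, preserving attributes.
rebuild_series <- function(template, rows) {
  out <- rows %>%
    mutate(
      day = match(.data$day, unique(.data$day)),
      epoch = dplyr::row_number()
    )
  attr(out, "start_time") <- attr(template, "start_time")
  attr(out, "epoch_len_s") <- epoch_len_s(template)
  if (!inherits(out, "epoch_series")) class(out) <- c("epoch_series", class(out))
  out
}

#' Read an epoch-count CSV
#'
#' Two dialects are supported. `generic` expects a header and three columns,
#' `subject_id,timestamp_iso8601,count`. `haukeland` expects a single column
#' of counts (one per minute, no header); subject id and start time come from
#' the arguments, mirroring datasets that ship counts with a sidecar config.
#' Counts are returned exactly as stored, without rescaling.
#'
#' @param path Path to the CSV file.
#' @param dialect `"generic"` or `"haukeland"`.
#' @param subject_id,start_time Metadata used by the `haukeland` dialect
#'   (ignored for `generic`, which carries both in the file).
#' @return An [epoch_series()].
#' @export
read_epoch_csv <- function(path,
                           dialect = c("generic", "haukeland"),
                           subject_id = "S1",
                           start_time = as.POSIXct("2020-01-01 00:00:00", tz = "UTC")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "generic") {
    if (length(lines) < 2) abort("no epochs")
    header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
    if (length(header) != 3) abort("parse error at line 1: expected 3 columns")
    body <- strsplit(lines[-1], ",", fixed = TRUE)
    bad <- which(lengths(body) != 3)
    if (length(bad)) abort(paste0("parse error at line ", bad[1] + 1, ": expected 3 columns"))
    counts <- suppressWarnings(as.numeric(vapply(body, `[[`, "", 3)))
    if (anyNA(counts)) {
      abort(paste0("parse error at line ", which(is.na(counts))[1] + 1, ": non-numeric count"))
    }
    subject_id <- body[[1]][1]
    start_time <- as.POSIXct(body[[1]][2], tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  } else {
    if (length(lines) == 0) abort("no epochs")
    counts <- suppressWarnings(as.numeric(lines))
    if (anyNA(counts)) {
      abort(paste0("parse error at line ", which(is.na(counts))[1], ": non-numeric count"))
    }
  }
  if (any(counts < 0)) {
    abort(paste0("validation error: negative count at epoch ", which(counts < 0)[1]))
  }
  epoch_series(counts, subject_id = subject_id, start_time = start_time)
}

#' Write an epoch-count CSV
#'
#' Inverse of [read_epoch_csv()]; the generic dialect round-trips
#' byte-identically for series written by this function.
#'
#' @param series An [epoch_series()].
#' @param path Output path.
#' @param dialect `"generic"` (subject, ISO-8601 timestamp, count) or
#'   `"haukeland"` (bare count column).
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path, dialect = c("generic", "haukeland")) {
  dialect <- match.arg(dialect)
  st <- attr(series, "start_time")
  els <- epoch_len_s(series)
  if (dialect == "generic") {
    ts <- format(st + (series$epoch - 1) * els, "%Y-%m-%dT%H:%M:%S")
    lines <- c(
      "subject_id,timestamp,count",
      paste(series$subject_id, ts, format(series$count, trim = TRUE, scientific = FALSE), sep = ",")
    )
  } else {
    lines <- format(series$count, trim = TRUE, scientific = FALSE)
  }
  writeLines(lines, path)
  invisible(path)
}
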