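#' Daily activity amplitude metrics: M10, L5, RA, ADAT
#'
#' Within each whole day, M10 is the largest mean over consecutive 10-hour
#' windows and L5 the smallest mean over consecutive 5-hour windows (windows
#' do not wrap across midnight); both are averaged over days. ADAT is the
#' grand mean of all counts, and RA = (M10 - L5) / (M10 + L5) is the relative
#' rest/activity amplitude in `[0, 1]`.
#'
#' @param series An [epoch_series()] with at least one whole day.
#' @param mode `"per_day"` (default) evaluates windows inside each day and
#'   averages across days; `"mean_profile"` first averages the daily profile
#'   across days and scans windows once.
#' @return A one-row tibble with columns `M10`, `L5`, `RA`, `ADAT`.
#' @export
m10_l5_ra_adat <- function(series, mode = c("per_day", "mean_profile")) {
  mode <- match.arg(mode)
  ppd <- epochs_per_day(series)
  els <- epoch_len_s(series)
  win10 <- as.integer(36000 / els)
  win5 <- as.integer(18000 / els)
  days <- split(series$count, series$day)
  days <- days[lengths(days) == ppd]
  if (length(days) == 0) abort("need at least one whole day")
  scan <- function(x, w, worst) {
    cs <- c(0, cumsum(x))
    means <- (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
    if (worst) min(means) else max(means)
  }
  if (mode == "per_day") {
    m10 <- mean(vapply(days, scan, numeric(1), w = win10, worst = FALSE))
    l5 <- mean(vapply(days, scan, numeric(1), w = win5, worst = TRUE))
  } else {
    prof <- rowMeans(do.call(cbind, days))
    m10 <- scan(prof, win10, worst = FALSE)
    l5 <- scan(prof, win5, worst = TRUE)
  }
  adat <- mean(unlist(days))
  ra <- if (m10 + l5 > 0) (m10 - l5) / (m10 + l5) else 0
  tibble::tibble(M10 = m10, L5 = l5, RA = ra, ADAT = adat)
}

#' Interdaily stability (IS)
#'
#' Ratio of the variance of the average daily profile to the total variance:
#' `IS = (N * sum_h (xbar_h - xbar)^2) / (p * sum_i (x_i - xbar)^2)`, where
#' the `x_i` are the counts at the analysis resolution, the `xbar_h` are the
#' `p` time-of-day means and `xbar` is the grand mean. 1 means a perfectly
#' repeated daily pattern; i.i.d. noise over `d` days gives about `1/d`.
#'
#' @param series An [epoch_series()] with at least two whole days.
#' @param profile `"minute"` (default, p = 1440 at 1-min epochs) keeps the
#'   native epoch resolution; `"hour"` first averages counts within each hour
#'   (p = 24), the classical variant.
#' @return IS in `[0, 1]`, or `NA` for a constant series.
#' @export
interdaily_stability <- function(series, profile = c("minute", "hour")) {
  profile <- match.arg(profile)
  ppd <- epochs_per_day(series)
  days <- split(series$count, series$day)
  days <- days[lengths(days) == ppd]
  if (length(days) < 2) abort("need at least two whole days")
  mat <- do.call(cbind, days)  # time-of-day x day
  if (profile == "hour") {
    per_hour <- as.integer(3600 / epoch_len_s(series))
    grp <- rep(seq_len(ppd / per_hour), each = per_hour)
    mat <- apply(mat, 2, function(col) vapply(split(col, grp), mean, numeric(1)))
  }
  x <- as.numeric(mat)
  n <- length(x)
  p <- nrow(mat)
  xbar <- mean(x)
  denom <- sum((x - xbar)^2)
  if (denom == 0) return(NA_real_)
  hourly <- rowMeans(mat)
  (n * sum((hourly - xbar)^2)) / (p * denom)
}

#' Intradaily variability (IV)
#'
#' Normalized mean square of successive differences,
#' `IV = (N * sum_{i>=2} (x_i - x_{i-1})^2) / ((N - 1) * sum_i (x_i - xbar)^2)`.
#' High values indicate a fragmented rhythm; a strictly alternating series
#' attains the maximum of 4 (as N grows; exactly 4 for even N).
#'
#' @param series An [epoch_series()] with at least two epochs.
#' @return IV in `[0, 4]`, or `NA` for a constant series.
#' @export
intradaily_variability <- function(series) {
  x <- series$count
  n <- length(x)
  if (n < 2) abort("need at least two epochs")
  denom <- sum((x - mean(x))^2)
  if (denom == 0) return(NA_real_)
  (n * sum(diff(x)^2)) / ((n - 1) * denom)
}

#' Global activity statistics
#'
#' @param series An [epoch_series()].
#' @return A one-row tibble with `activity_mean`, `activity_std` (population
#'   standard deviation) and `zero_ratio` (fraction of epochs equal to zero).
#' @export
global_stats <- function(series) {
  x <- series$count
  tibble::tibble(
    activity_mean = mean(x),
    activity_std = sd_pop(x),
    zero_ratio = mean(x == 0)
  )
}

#' Sleep fragmentation index of one night
#'
#' Fraction of a sleep bout spent in movement, where movement is any epoch
#' with a positive count plus any short immobile gap (zero-run of length at
#' most `short_immobile_max` epochs) between movements.
#'
#' @param night Numeric counts inside one sleep interval, or a
#'   `night_activity` list from [night_slices()].
#' @param short_immobile_max Longest zero-run still counted as movement
#'   (default 2 epochs).
#' @return FI in `[0, 1]`.
#' @export
fragmentation_index <- function(night, short_immobile_max = 2L) {
  counts <- if (is.list(night)) night$counts else night
  if (length(counts) == 0) abort("night is empty")
  mobile <- counts > 0
  r <- runs_of(mobile)
  active <- sum(r$length[r$value])
  short_gaps <- sum(r$length[!r$value & r$length <= short_immobile_max])
  (active + short_gaps) / length(counts)
}

#' All circadian and global features for one subject
#'
#' Combines [m10_l5_ra_adat()], [interdaily_stability()],
#' [intradaily_variability()], [global_stats()], the per-night
#' [fragmentation_index()] summarized as mean/SD (`FI_m`, `FI_std`), and mean
#' sleep time `slp_tm`. Undefined metrics (constant series, no valid nights)
#' propagate as `NA` and are imputed downstream.
#'
#' @param series The subject's [epoch_series()] (whole days).
#' @param nights List of nights from [night_slices()].
#' @param intervals Valid sleep intervals (for `slp_tm`).
#' @param short_immobile_max Passed to [fragmentation_index()].
#' @inheritParams interdaily_stability
#' @return A one-row tibble of named features.
#' @export
circadian_features <- function(series, nights, intervals,
                               short_immobile_max = 2L,
                               profile = "minute") {
  amp <- m10_l5_ra_adat(series)
  is_v <- tryCatch(interdaily_stability(series, profile = profile),
                   error = function(e) NA_real_)
  iv_v <- tryCatch(intradaily_variability(series), error = function(e) NA_real_)
  gs <- global_stats(series)
  fi <- vapply(nights, fragmentation_index, numeric(1),
               short_immobile_max = short_immobile_max)
  dplyr::bind_cols(
    amp,
    tibble::tibble(IS = is_v, IV = iv_v),
    gs,
    tibble::tibble(
      FI_m = if (length(fi)) mean(fi) else NA_real_,
      FI_std = if (length(fi)) sd_pop(fi) else NA_real_,
      slp_tm = sleep_time(intervals)
    )
  )
}
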