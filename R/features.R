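#' Extract the full feature table for a cohort
#'
#' Runs the whole feature-engineering pipeline per subject: sleep detection
#' and validity filtering, circadian/global metrics, nocturnal peak taxonomy
#' and wavelet structure factors, and returns one row per subject with the
#' binary group label attached. Metrics undefined for a subject (no valid
#' nights, constant series) are `NA`; see [impute_features()].
#'
#' @param cohort An `acti_cohort` from [generate_cohort()], or a named list
#'   of [epoch_series()] plus a `labels` tibble.
#' @param labels Tibble `subject_id`, `label`; unnecessary when `cohort` is
#'   an `acti_cohort`.
#' @param params A [sleep_params()].
#' @param short_immobile_max,close_gap_max,profile Feature options passed
#'   through to the per-subject extractors.
#' @param wavelet Include wavelet features (default `TRUE`).
#' @return A `feature_table` tibble: `subject_id`, `label`, then features.
#' @export
extract_features <- function(cohort, labels = NULL,
                             params = sleep_params(),
                             short_immobile_max = 2L, close_gap_max = 2L,
                             profile = "minute", wavelet = TRUE) {
  if (inherits(cohort, "acti_cohort")) {
    labels <- cohort$labels
    series_list <- cohort$series
  } else {
    series_list <- cohort
    if (is.null(labels)) abort("labels required when cohort is a plain list")
  }
  rows <- purrr::imap(series_list, function(series, id) {
    ivs <- filter_valid_sleep(detect_sleep(series, params), params)
    nights <- night_slices(series, ivs)
    circ <- circadian_features(series, nights, ivs,
                               short_immobile_max = short_immobile_max,
                               profile = profile)
    pk <- if (length(nights)) {
      peak_features(nights, close_gap_max = close_gap_max)
    } else {
      tibble::as_tibble(as.list(setNames(
        rep(NA_real_, length(peak_feature_names())), peak_feature_names())))
    }
    out <- dplyr::bind_cols(tibble::tibble(subject_id = id), circ, pk)
    if (wavelet) {
      wv <- if (length(nights)) wavelet_features(nights) else
        tibble::tibble(structure_pms = NA_real_, wavelet_fi = NA_real_)
      out <- dplyr::bind_cols(out, wv)
    }
    out
  })
  tbl <- left_join(labels, bind_rows(rows), by = "subject_id")
  class(tbl) <- c("feature_table", class(tbl))
  tbl
}

#' Feature columns of a feature table
#' @param table A `feature_table` tibble.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("subject_id", "label"))
}

#' Drop over-missing features and impute the rest
#'
#' Features missing in more than `missing_max` of subjects are dropped;
#' remaining missing values are replaced by the median of the feature within
#' the subject's group, falling back to the overall median when a whole
#' group is missing.
#'
#' @param table A `feature_table`.
#' @param missing_max Maximum tolerated missing fraction (default 0.2).
#' @return The imputed `feature_table`.
#' @export
impute_features <- function(table, missing_max = 0.2) {
  feats <- feature_names(table)
  miss <- vapply(table[feats], function(x) mean(is.na(x)), numeric(1))
  keep <- feats[miss <= missing_max]
  out <- table[, c("subject_id", "label", keep)]
  for (f in keep) {
    x <- out[[f]]
    if (!anyNA(x)) next
    for (g in unique(out$label)) {
      sel <- out$label == g & is.na(x)
      if (any(sel)) {
        m <- median(x[out$label == g], na.rm = TRUE)
        if (is.na(m)) m <- median(x, na.rm = TRUE)
        x[sel] <- m
      }
    }
    out[[f]] <- x
  }
  class(out) <- c("feature_table", class(out))
  out
}
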