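# ggplot2 displays for the main result types.

#' Plot a double-plotted-style actogram of an epoch series
#'
#' One ribbon per day, activity counts against time of day; sleep intervals
#' can be shaded for visual inspection of the detector.
#'
#' @param series An [epoch_series()].
#' @param intervals Optional sleep intervals from [detect_sleep()].
#' @return A ggplot object.
#' @export
plot_actogram <- function(series, intervals = NULL) {
  ppd <- epochs_per_day(series)
  df <- mutate(series, tod = (.data$epoch - 1) %% ppd / (ppd / 24))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tod, y = .data$count)) +
    ggplot2::geom_col(width = 24 / ppd, fill = "grey25") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$day)) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "time of day (h)", y = "activity (counts/min)")
  if (!is.null(intervals) && nrow(intervals)) {
    shade <- intervals %>%
      mutate(day = (.data$start_epoch - 1) %/% ppd + 1,
             from = (.data$start_epoch - 1) %% ppd / (ppd / 24),
             to = pmin(24, .data$from + .data$duration_min / 60))
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$from, xmax = .data$to, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.25
    )
  }
  p
}

# Shared beeswarm-style SHAP summary: one jittered point per pooled
# (subject, model, feature) pair, colored by the feature value scaled within
# feature.
shap_summary_plot <- function(aggregated, top_n = 15) {
  top <- head(aggregated$ranking$feature, top_n)
  df <- aggregated$pooled %>%
    filter(.data$feature %in% top) %>%
    group_by(.data$feature) %>%
    mutate(value_scaled = if (diff(range(.data$feature_value)) > 0) {
      (.data$feature_value - min(.data$feature_value)) /
        diff(range(.data$feature_value))
    } else 0.5) %>%
    ungroup() %>%
    mutate(feature = factor(.data$feature, levels = rev(top)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shap_value, y = .data$feature,
                                   color = .data$value_scaled)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, size = 0.8, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::scale_color_gradient(low = "#2166ac", high = "#b2182b",
                                  name = "feature value\n(scaled)") +
    ggplot2::labs(x = "Shapley value (probability scale)", y = NULL)
}

#' SHAP summary plot of a clique-selection result
#' @param object A `cffs_result` with retained models.
#' @param top_n Features to display (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cffs_result <- function(object, top_n = 15, ...) {
  if (is.null(object$aggregated)) abort("no retained models to plot")
  shap_summary_plot(object$aggregated, top_n)
}

#' SHAP summary plot of a hybrid-selection result
#' @param object An `ahfs_result`.
#' @param top_n Features to display (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ahfs_result <- function(object, top_n = 15, ...) {
  shap_summary_plot(object$aggregated, top_n)
}

#' Structure-parameter curve of a wavelet map
#' @param object A `structure_result` from [structure_params()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.structure_result <- function(object, ...) {
  ggplot2::ggplot(object$per_scale,
                  ggplot2::aes(x = .data$scale, y = .data$structure)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "scale (epochs)", y = "structure parameter")
}
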