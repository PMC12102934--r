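#' Tidy a clique-selection result
#'
#' @param x A `cffs_result`.
#' @param what `"ranking"` (default) for the pooled Shapley ranking,
#'   `"models"` for one row per trained clique model, `"screen"` for the
#'   screening table.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cffs_result <- function(x, what = c("ranking", "models", "screen"), ...) {
  what <- match.arg(what)
  switch(what,
    ranking = x$ranking,
    screen = x$screen_table,
    models = bind_rows(purrr::map(x$results, function(r) {
      tibble::tibble(clique = paste(r$clique, collapse = "+"),
                     size = length(r$clique), algorithm = r$algorithm,
                     cv_accuracy = r$cv_accuracy,
                     retained = r$cv_accuracy >= 0.60)
    }))
  )
}

#' One-row summary of a clique-selection result
#'
#' @param x A `cffs_result`.
#' @param ... Unused.
#' @return A one-row tibble with feature, clique and model counts.
#' @export
glance.cffs_result <- function(x, ...) {
  tibble::tibble(
    n_screened = length(x$screened),
    n_cliques = length(x$cliques),
    n_models = length(x$results),
    n_retained = length(x$retained),
    min_retained_accuracy = if (length(x$retained)) {
      min(vapply(x$retained, `[[`, numeric(1), "cv_accuracy"))
    } else NA_real_
  )
}

#' Tidy a hybrid-selection result
#'
#' @param x An `ahfs_result`.
#' @param what `"ranking"` (default) or `"trace"` (run x step selections
#'   with accuracies).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ahfs_result <- function(x, what = c("ranking", "trace"), ...) {
  what <- match.arg(what)
  if (what == "ranking") x$ranking else x$trace
}

#' One-row summary of a hybrid-selection result
#'
#' @param x An `ahfs_result`.
#' @param ... Unused.
#' @return A one-row tibble with slot/model counts and best accuracies.
#' @export
glance.ahfs_result <- function(x, ...) {
  tibble::tibble(
    n_runs = length(x$runs),
    n_slots = x$n_slots,
    best_models = x$best_models,
    mean_best_accuracy = mean(vapply(x$runs, function(r) {
      r$step_accuracy[r$best_step]
    }, numeric(1)))
  )
}
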