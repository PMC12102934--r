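#' Screening parameters for clique-forming feature selection
#'
#' @param welch_alpha Welch two-sample t-test significance level (default
#'   0.05).
#' @param mi_min Minimum mutual information with the label, in nats (default
#'   0.05, above the plug-in estimator's bias of about `(B-1)/(2n)` nats at
#'   the default bin count and cohort size, so the MI arm rejects
#'   label-independent features rather than passing them on estimation bias).
#' @param missing_max Maximum tolerated missing fraction per feature before
#'   imputation (default 0.2).
#' @param bins Equal-frequency bins for the MI estimate (default 4).
#' @return A `screen_params` list.
#' @export
screen_params <- function(welch_alpha = 0.05, mi_min = 0.05,
                          missing_max = 0.2, bins = 4L) {
  stopifnot(welch_alpha > 0, welch_alpha < 1, mi_min >= 0)
  structure(list(welch_alpha = welch_alpha, mi_min = mi_min,
                 missing_max = missing_max, bins = bins),
            class = "screen_params")
}

#' Screen features by Welch test and mutual information
#'
#' A feature is kept when its Welch two-sample t-test between groups has
#' `p < welch_alpha` and its mutual information with the label is at least
#' `mi_min` nats. Screening generates candidates for the clique graph, so no
#' multiple-testing correction is applied. Constant features (Welch
#' undefined, MI 0) are dropped.
#'
#' @param table An imputed `feature_table` (see [impute_features()]).
#' @param params A [screen_params()].
#' @return A tibble `feature`, `welch_p`, `mi`, `keep`; screened features
#'   are `feature[keep]`.
#' @export
screen_features <- function(table, params = screen_params()) {
  y <- table$label
  stopifnot(sum(y == 0) >= 2, sum(y == 1) >= 2)
  feats <- feature_names(table)
  rows <- purrr::map(feats, function(f) {
    x <- table[[f]]
    x0 <- x[y == 0]
    x1 <- x[y == 1]
    p <- tryCatch(t.test(x0, x1, var.equal = FALSE)$p.value,
                  error = function(e) NA_real_)
    if (is.na(p) && sd(x0) == 0 && sd(x1) == 0 && mean(x0) != mean(x1)) {
      # both groups constant at different values: perfect separation, the
      # t statistic degenerates but the evidence is maximal
      p <- 0
    }
    mi <- mutual_information(x, y, bins = params$bins)
    tibble::tibble(feature = f, welch_p = p, mi = mi,
                   keep = !is.na(p) && p < params$welch_alpha && mi >= params$mi_min)
  })
  bind_rows(rows)
}

#' Build the low-correlation feature graph
#'
#' Vertices are the screened features; an edge joins two features when the
#' magnitude of their Pearson correlation is at most `corr_max`, so that a
#' clique is a set of mutually weakly correlated features. A zero-variance
#' feature is treated as fully correlated with everything (no edges).
#'
#' @param table An imputed `feature_table`.
#' @param screened Character vector of screened feature names.
#' @param corr_max Correlation-magnitude threshold for keeping an edge
#'   (default 0.5, i.e. linked features share at most a quarter of their
#'   variance; screened feature sets are dominated by a few latent factors,
#'   and tighter thresholds regularly leave the graph without any clique of
#'   three or more features).
#' @return An [igraph::graph] with a `name` vertex attribute.
#' @export
build_feature_graph <- function(table, screened, corr_max = 0.5) {
  stopifnot(length(screened) >= 2)
  X <- as.matrix(table[, screened])
  sds <- apply(X, 2, sd_pop)
  R <- suppressWarnings(cor(X))
  R[is.na(R)] <- 1
  R[sds == 0, ] <- 1
  R[, sds == 0] <- 1
  A <- (abs(R) <= corr_max)
  diag(A) <- FALSE
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

#' Enumerate feature cliques in a size band
#'
#' By default returns the maximal cliques whose size lies in
#' `[size_min, size_max]`; with `expand_subcliques = TRUE` returns every
#' clique in the band (sub-cliques included). Output order is deterministic:
#' features sorted within a clique, cliques sorted lexicographically.
#'
#' @param graph Graph from [build_feature_graph()].
#' @param size_min,size_max Clique size band (defaults 3 and 6).
#' @param expand_subcliques Enumerate all cliques in the band instead of
#'   maximal ones only (default `FALSE`).
#' @return A list of character vectors of feature names (possibly empty).
#' @export
enumerate_cliques <- function(graph, size_min = 3L, size_max = 6L,
                              expand_subcliques = FALSE) {
  raw <- if (expand_subcliques) {
    igraph::cliques(graph, min = size_min, max = size_max)
  } else {
    igraph::max_cliques(graph, min = size_min, max = size_max)
  }
  cl <- purrr::map(raw, function(v) sort(igraph::V(graph)$name[as.integer(v)]))
  key <- vapply(cl, paste, "", collapse = "\r")
  cl[order(key)]
}

#' Train one clique model with cross-validated accuracy and exact Shapley
#' values
#'
#' Fits the requested algorithm on the clique's features under stratified
#' 3-fold cross-validation (features standardized inside training folds),
#' then refits on all subjects and computes exact Shapley values of the
#' class-1 probability by subset enumeration, with the feature means as
#' background.
#'
#' @param table An imputed `feature_table`.
#' @param clique Character vector of feature names.
#' @param algorithm `"LR"`, `"RF"` or `"ANN"`.
#' @param folds CV folds (default 3).
#' @param seed Integer seed.
#' @param opts Model hyper-parameters, see `default_model_opts()`.
#' @return A `cffs_model` list (`clique`, `algorithm`, `cv_accuracy`,
#'   `shap`, `fold_assignments`, `seed`, fitted `model`), or `NULL` when CV
#'   folds degenerate repeatedly.
#' @export
train_clique <- function(table, clique, algorithm, folds = 3L, seed = 1L,
                         opts = default_model_opts()) {
  stopifnot(length(clique) >= 1)
  X <- as.matrix(table[, clique])
  y <- table$label
  cv <- cv_accuracy(X, y, algorithm, folds = folds, seed = seed, opts = opts)
  if (is.null(cv)) return(NULL)
  final <- fit_model(X, y, algorithm, seed = derive_seed(seed, 303L), opts = opts)
  shap <- shapley_exact(final, X)
  structure(list(clique = clique, algorithm = algorithm,
                 cv_accuracy = cv$cv_accuracy, shap = shap,
                 fold_assignments = cv$fold_assignments, seed = seed,
                 model = final),
            class = "cffs_model")
}

#' Keep models at or above the accuracy gate
#'
#' @param results List of `cffs_model`s.
#' @param min_accuracy Gate on cross-validated accuracy, boundary inclusive
#'   (default 0.60).
#' @return The retained models.
#' @export
filter_models <- function(results, min_accuracy = 0.60) {
  purrr::keep(results, function(r) r$cv_accuracy >= min_accuracy)
}

#' Pool Shapley values across retained models
#'
#' Concatenates the per-subject (feature value, Shapley value) pairs of each
#' feature over all models that contain it, and ranks features by the mean
#' absolute pooled Shapley value.
#'
#' @param retained List of retained models (`cffs_model` or the best models
#'   of hybrid-selection runs).
#' @param table The `feature_table` the models were trained on.
#' @return An `aggregated_shap` list with tibbles `pooled` (`model_id`,
#'   `feature`, `subject_id`, `feature_value`, `shap_value`) and `ranking`
#'   (`rank`, `feature`, `mean_abs_shap`, `n_pooled`).
#' @export
aggregate_shap <- function(retained, table) {
  stopifnot(length(retained) >= 1)
  pooled <- bind_rows(purrr::imap(retained, function(r, i) {
    feats <- colnames(r$shap)
    n <- nrow(r$shap)
    tibble::tibble(model_id = i,
                   feature = rep(feats, each = n),
                   subject_id = rep(table$subject_id, length(feats)),
                   feature_value = as.vector(as.matrix(table[, feats])),
                   shap_value = as.vector(r$shap))
  }))
  ranking <- pooled %>%
    group_by(.data$feature) %>%
    summarise(mean_abs_shap = mean(abs(.data$shap_value)),
              n_pooled = n(), .groups = "drop") %>%
    arrange(desc(.data$mean_abs_shap), .data$feature) %>%
    mutate(rank = dplyr::row_number()) %>%
    select("rank", "feature", "mean_abs_shap", "n_pooled")
  structure(list(pooled = pooled, ranking = ranking), class = "aggregated_shap")
}

#' Run the full clique-forming feature-selection pipeline
#'
#' Screens features (Welch + mutual information), builds the
#' low-correlation graph, enumerates cliques in the size band, trains each
#' clique with every requested algorithm under 3-fold CV, filters at the
#' accuracy gate and pools Shapley values.
#'
#' @param table A `feature_table`; imputed automatically if it contains
#'   missing values.
#' @param screen A [screen_params()].
#' @param corr_max Edge threshold of the feature graph (default 0.5).
#' @param size_min,size_max Clique size band (defaults 3, 6).
#' @param expand_subcliques See [enumerate_cliques()].
#' @param algorithms Algorithms to train per clique (default LR, RF, ANN).
#' @param folds CV folds (default 3).
#' @param min_accuracy Accuracy gate (default 0.60).
#' @param max_cliques Upper bound on cliques trained per run (default 300).
#'   Clique counts depend steeply on how many weakly correlated feature axes
#'   survive screening and can explode into the thousands; when the
#'   enumeration exceeds the bound, a seeded uniform subsample of that size
#'   is trained instead, keeping model counts at the few-hundred scale the
#'   framework is designed around.
#' @param seed Master seed.
#' @param opts Model hyper-parameters.
#' @return A `cffs_result` list: `screen_table`, `screened`, `graph`,
#'   `cliques`, `results`, `retained`, `aggregated`, `ranking`, `seed`.
#' @export
run_cffs <- function(table, screen = screen_params(), corr_max = 0.5,
                     size_min = 3L, size_max = 6L, expand_subcliques = FALSE,
                     algorithms = c("LR", "RF", "ANN"), folds = 3L,
                     min_accuracy = 0.60, max_cliques = 300L, seed = 1L,
                     opts = default_model_opts()) {
  if (anyNA(table[feature_names(table)])) {
    table <- impute_features(table, missing_max = screen$missing_max)
  }
  st <- screen_features(table, screen)
  screened <- st$feature[st$keep]
  empty <- structure(list(screen_table = st, screened = screened,
                          graph = NULL, cliques = list(), results = list(),
                          retained = list(), aggregated = NULL,
                          ranking = tibble::tibble(rank = integer(),
                                                   feature = character(),
                                                   mean_abs_shap = numeric(),
                                                   n_pooled = integer()),
                          seed = seed),
                     class = "cffs_result")
  if (length(screened) < 2) return(empty)
  graph <- build_feature_graph(table, screened, corr_max = corr_max)
  cliques <- enumerate_cliques(graph, size_min = size_min, size_max = size_max,
                               expand_subcliques = expand_subcliques)
  empty$graph <- graph
  if (length(cliques) == 0) return(empty)
  if (length(cliques) > max_cliques) {
    pick <- with_seed(derive_seed(seed, 909L),
                      sort(sample.int(length(cliques), max_cliques)))
    cliques <- cliques[pick]
  }
  jobs <- expand.grid(clique = seq_along(cliques), algorithm = algorithms,
                      stringsAsFactors = FALSE)
  results <- purrr::pmap(jobs, function(clique, algorithm) {
    train_clique(table, cliques[[clique]], algorithm, folds = folds,
                 seed = derive_seed(seed, clique, match(algorithm, c("LR", "RF", "ANN"))),
                 opts = opts)
  })
  results <- purrr::keep(results, Negate(is.null))
  retained <- filter_models(results, min_accuracy = min_accuracy)
  aggregated <- if (length(retained)) aggregate_shap(retained, table) else NULL
  structure(list(screen_table = st, screened = screened, graph = graph,
                 cliques = cliques, results = results, retained = retained,
                 aggregated = aggregated,
                 ranking = if (is.null(aggregated)) empty$ranking else aggregated$ranking,
                 seed = seed),
            class = "cffs_result")
}

#' Write the pooled ranking of a selection result to CSV
#'
#' Deterministic output: a fixed master seed reproduces the file
#' byte-identically.
#'
#' @param result A `cffs_result` or `ahfs_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(result, path) {
  rk <- result$ranking
  lines <- c("rank,feature,mean_abs_shap,n_pooled",
             sprintf("%d,%s,%.12g,%d", rk$rank, rk$feature,
                     rk$mean_abs_shap, rk$n_pooled))
  writeLines(lines, path)
  invisible(path)
}
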