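#' Parameters of adaptive hybrid feature selection
#'
#' AHFS is a greedy forward selection: at every step each configured measure
#' proposes its best-scoring remaining feature, and a small neural network
#' arbitrates among the deduplicated candidates by cross-validated accuracy.
#' The procedure is repeated over independent runs to average out the
#' network's initialization randomness.
#'
#' @param n_runs Independent runs (default 20).
#' @param n_steps Features added per run (default 20).
#' @param measures Candidate-proposing measures, a subset of
#'   `MIM, mRMR, JMI, MMIFS, LCFS` (default all five).
#' @param ann_hidden Hidden units of the evaluator network (default 2; a
#'   larger evaluator overfits cohorts of this size).
#' @param ann_maxit,ann_decay,ann_reltol Evaluator training limits: at most
#'   300 iterations, weight decay 1e-3, early stop at relative tolerance
#'   1e-4.
#' @param beta Redundancy weight of MMIFS (default 0.5).
#' @param bins Equal-frequency bins for MI estimates (default 4).
#' @param n_perm Permutations for sampled Shapley values (default 256).
#' @param folds CV folds (default 3).
#' @return An `ahfs_params` list.
#' @export
ahfs_params <- function(n_runs = 20L, n_steps = 20L,
                        measures = c("MIM", "mRMR", "JMI", "MMIFS", "LCFS"),
                        ann_hidden = 2L, ann_maxit = 300L, ann_decay = 1e-3,
                        ann_reltol = 1e-4,
                        beta = 0.5, bins = 4L, n_perm = 256L, folds = 3L) {
  stopifnot(n_runs >= 1, n_steps >= 1, ann_hidden >= 1)
  measures <- match.arg(measures, several.ok = TRUE)
  structure(list(n_runs = as.integer(n_runs), n_steps = as.integer(n_steps),
                 measures = measures, ann_hidden = as.integer(ann_hidden),
                 ann_maxit = as.integer(ann_maxit), ann_decay = ann_decay,
                 ann_reltol = ann_reltol,
                 beta = beta, bins = as.integer(bins),
                 n_perm = as.integer(n_perm), folds = as.integer(folds)),
            class = "ahfs_params")
}

#' Candidate features proposed by the measures
#'
#' Each measure scores every remaining feature given the selected set and
#' proposes its argmax (ties broken alphabetically); proposals are
#' deduplicated and returned sorted.
#'
#' @param table An imputed `feature_table`.
#' @param selected Character vector of already-selected features.
#' @param remaining Character vector of candidate features.
#' @param measures Measure names.
#' @param beta,bins See [ahfs_params()].
#' @param ctx Optional precomputed MI context (internal reuse).
#' @return Character vector of candidate features.
#' @export
candidate_set <- function(table, selected, remaining,
                          measures = c("MIM", "mRMR", "JMI", "MMIFS", "LCFS"),
                          beta = 0.5, bins = 4L, ctx = NULL) {
  stopifnot(length(remaining) >= 1)
  if (is.null(ctx)) ctx <- mi_context(table, bins = bins)
  remaining <- sort(remaining)
  props <- vapply(measures, function(m) {
    sc <- measure_scores(ctx, m, selected, remaining, beta = beta)
    remaining[which.max(sc)]  # which.max takes the earliest = alphabetical tie-break
  }, character(1))
  sort(unique(unname(props)))
}

#' One greedy extension step
#'
#' Trains the evaluator network on `selected + candidate` for every
#' candidate under stratified CV and picks the candidate with the highest
#' mean accuracy (ties to the alphabetically lower name). Candidates whose
#' CV degenerates are skipped.
#'
#' @param table An imputed `feature_table`.
#' @param selected Already-selected features.
#' @param candidates Candidate features from [candidate_set()].
#' @param params An [ahfs_params()].
#' @param seed Integer seed.
#' @param evaluator Model family arbitrating candidates (default `"ANN"`;
#'   `"LR"` is a deterministic hook for oracle tests).
#' @return List with `feature` and `accuracy`.
#' @export
ahfs_step <- function(table, selected, candidates, params = ahfs_params(),
                      seed = 1L, evaluator = "ANN") {
  stopifnot(length(candidates) >= 1)
  y <- table$label
  opts <- default_model_opts()
  opts$ann_hidden <- params$ann_hidden
  opts$ann_maxit <- params$ann_maxit
  opts$ann_decay <- params$ann_decay
  opts$ann_reltol <- params$ann_reltol
  candidates <- sort(candidates)
  accs <- vapply(candidates, function(f) {
    X <- as.matrix(table[, c(selected, f)])
    cv <- cv_accuracy(X, y, evaluator, folds = params$folds,
                      seed = derive_seed(seed, 11L), opts = opts)
    if (is.null(cv)) NA_real_ else cv$cv_accuracy
  }, numeric(1))
  if (all(is.na(accs))) abort("all candidates failed evaluation")
  best <- which.max(accs)  # earliest max = alphabetical tie-break
  list(feature = candidates[best], accuracy = unname(accs[best]))
}

#' One full AHFS run
#'
#' Performs `n_steps` greedy extensions, records the accuracy trajectory,
#' refits the best-accuracy step's model on all data and explains it with
#' sampled Shapley values.
#'
#' @param table An imputed `feature_table`.
#' @param params An [ahfs_params()].
#' @param run_seed Integer seed of this run.
#' @param evaluator See [ahfs_step()].
#' @param ctx Optional precomputed MI context (internal reuse).
#' @return An `ahfs_run` list: `selected` (ordered, distinct),
#'   `step_accuracy`, `best_step`, `shap` (subjects x best-step features),
#'   fitted `model`, `seed`.
#' @export
ahfs_run <- function(table, params = ahfs_params(), run_seed = 1L,
                     evaluator = "ANN", ctx = NULL) {
  feats <- feature_names(table)
  if (length(feats) < params$n_steps) {
    abort("fewer features than n_steps")
  }
  if (is.null(ctx)) ctx <- mi_context(table, bins = params$bins)
  selected <- character()
  step_accuracy <- numeric(params$n_steps)
  for (k in seq_len(params$n_steps)) {
    remaining <- setdiff(feats, selected)
    cands <- candidate_set(table, selected, remaining,
                           measures = params$measures, beta = params$beta,
                           bins = params$bins, ctx = ctx)
    step <- ahfs_step(table, selected, cands, params = params,
                      seed = derive_seed(run_seed, k), evaluator = evaluator)
    selected <- c(selected, step$feature)
    step_accuracy[k] <- step$accuracy
  }
  best_step <- which.max(step_accuracy)
  best_feats <- selected[seq_len(best_step)]
  opts <- default_model_opts()
  opts$ann_hidden <- params$ann_hidden
  opts$ann_maxit <- params$ann_maxit
  opts$ann_decay <- params$ann_decay
  opts$ann_reltol <- params$ann_reltol
  X <- as.matrix(table[, best_feats, drop = FALSE])
  model <- fit_model(X, table$label, evaluator,
                     seed = derive_seed(run_seed, 404L), opts = opts)
  shap <- shapley_sampled(model, X, n_perm = params$n_perm,
                          seed = derive_seed(run_seed, 505L))
  structure(list(selected = selected, step_accuracy = step_accuracy,
                 best_step = best_step, shap = shap, model = model,
                 seed = run_seed),
            class = "ahfs_run")
}

#' Run the AHFS ensemble
#'
#' Executes `n_runs` independent runs (seeds derived from the master seed),
#' giving `n_runs * n_steps` selected-feature slots and one best model per
#' run, whose sampled Shapley matrices are pooled exactly as in the clique
#' framework.
#'
#' @param table A `feature_table`; imputed automatically if needed.
#' @param params An [ahfs_params()].
#' @param seed Master seed.
#' @param evaluator See [ahfs_step()].
#' @return An `ahfs_result` list: `runs` (list of `ahfs_run`), `trace`
#'   (tibble `run`, `step`, `feature`, `accuracy`), `n_slots`, `best_models`,
#'   `aggregated`, `ranking`, `seed`.
#' @export
run_ahfs <- function(table, params = ahfs_params(), seed = 1L,
                     evaluator = "ANN") {
  if (anyNA(table[feature_names(table)])) table <- impute_features(table)
  ctx <- mi_context(table, bins = params$bins)
  runs <- purrr::map(seq_len(params$n_runs), function(r) {
    ahfs_run(table, params = params, run_seed = derive_seed(seed, 7000L, r),
             evaluator = evaluator, ctx = ctx)
  })
  trace <- bind_rows(purrr::imap(runs, function(r, i) {
    tibble::tibble(run = i, step = seq_along(r$selected),
                   feature = r$selected, accuracy = r$step_accuracy)
  }))
  aggregated <- aggregate_shap(runs, table)
  structure(list(runs = runs, trace = trace,
                 n_slots = nrow(trace), best_models = length(runs),
                 aggregated = aggregated, ranking = aggregated$ranking,
                 seed = seed),
            class = "ahfs_result")
}
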