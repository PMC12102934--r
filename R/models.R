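# One interface over the three classifier families used by the selection
# frameworks. All fits standardize features with statistics estimated on the
# training rows only (no leakage across CV folds) and are seeded.

default_model_opts <- function() {
  list(ann_hidden = 8L, ann_decay = 1e-3, ann_maxit = 500L,
       ann_reltol = 1e-8, rf_trees = 200L, lr_C = 1)
}

# Fit one classifier on a raw feature matrix. Returns a model object whose
# predictions are probabilities of class 1.
fit_model <- function(X, y, algorithm = c("LR", "RF", "ANN"), seed = 1L,
                      opts = default_model_opts()) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd_pop)
  scl[scl == 0] <- 1
  Z <- scale(X, center = ctr, scale = scl)
  fit <- with_seed(seed, switch(algorithm,
    LR = {
      if (ncol(Z) >= 2) {
        # small-fold class-count advisories are expected at toy sizes
        g <- suppressWarnings(
          glmnet::glmnet(Z, y, family = "binomial", alpha = 0,
                         lambda = 1 / (opts$lr_C * nrow(Z)),
                         standardize = FALSE))
        # keep the linear predictor only: plain matrix math at predict time
        list(intercept = as.numeric(g$a0), beta = as.numeric(g$beta[, 1]))
      } else {
        df <- data.frame(y = y, x = Z[, 1])
        g <- suppressWarnings(stats::glm(y ~ x, data = df,
                                         family = stats::binomial()))
        co <- unname(stats::coef(g))
        list(intercept = co[1], beta = co[2])
      }
    },
    RF = randomForest::randomForest(Z, factor(y, levels = c(0, 1)),
                                    ntree = opts$rf_trees),
    ANN = nnet::nnet(Z, matrix(y, ncol = 1), size = opts$ann_hidden,
                     decay = opts$ann_decay, maxit = opts$ann_maxit,
                     reltol = opts$ann_reltol, entropy = TRUE, trace = FALSE)
  ))
  structure(list(algorithm = algorithm, fit = fit, center = ctr, scale = scl,
                 features = colnames(X)),
            class = "acti_model")
}

# Probability of class 1 for raw (unstandardized) feature rows.
predict_prob <- function(model, X) {
  X <- as.matrix(X)
  Z <- scale(X, center = model$center, scale = model$scale)
  p <- switch(model$algorithm,
    LR = as.numeric(stats::plogis(model$fit$intercept + Z %*% model$fit$beta)),
    RF = as.numeric(predict(model$fit, newdata = Z, type = "prob")[, "1"]),
    ANN = as.numeric(predict(model$fit, Z))
  )
  unname(p)
}

# Stratified k-fold assignment.
make_folds <- function(y, k = 3L, seed = 1L) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

# Stratified k-fold CV accuracy (fraction correct at the 0.5 threshold).
# Folds with a single class are re-drawn with a fresh seed, up to
# max_attempts; failure returns NULL so callers can skip the candidate.
cv_accuracy <- function(X, y, algorithm, folds = 3L, seed = 1L,
                        opts = default_model_opts(), max_attempts = 10L) {
  X <- as.matrix(X)
  for (attempt in seq_len(max_attempts)) {
    fold <- make_folds(y, folds, derive_seed(seed, 101L, attempt))
    ok <- all(vapply(seq_len(folds),
                     function(f) length(unique(y[fold != f])) == 2,
                     logical(1)))
    if (!ok) next
    acc <- vapply(seq_len(folds), function(f) {
      train <- fold != f
      m <- fit_model(X[train, , drop = FALSE], y[train], algorithm,
                     seed = derive_seed(seed, 202L, f), opts = opts)
      p <- predict_prob(m, X[!train, , drop = FALSE])
      mean((p >= 0.5) == (y[!train] == 1))
    }, numeric(1))
    return(list(cv_accuracy = mean(acc), fold_assignments = fold))
  }
  NULL
}
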