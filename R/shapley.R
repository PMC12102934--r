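# Shapley-value attribution for small fitted models. The value function of a
# coalition S is the model's class-1 probability with features outside S
# replaced by a single background reference (the training-data feature
# means), so the efficiency axiom reads
#   sum_j phi_ij = f(x_i) - f(background).

#' Exact Shapley values by subset enumeration
#'
#' Enumerates all `2^p` coalitions, feasible for the small feature sets used
#' by clique models (p <= 6 or so). Satisfies efficiency to numerical
#' precision and the dummy axiom exactly (a feature equal to its background
#' value receives 0).
#'
#' @param model An internal fitted model (with `predict_prob()` semantics),
#'   or any function mapping a raw feature matrix to probabilities.
#' @param X Raw feature matrix (subjects x features) to explain.
#' @param background Numeric vector of reference feature values; defaults to
#'   `colMeans(X)`.
#' @return Matrix of Shapley values, same shape and dimnames as `X`.
#' @export
shapley_exact <- function(model, X, background = NULL) {
  f <- if (is.function(model)) model else function(M) predict_prob(model, M)
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(background)) background <- colMeans(X)
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  colnames(masks) <- colnames(X)
  n_mask <- nrow(masks)
  # stack all masked subject rows and predict once
  big <- matrix(rep(background, each = n_mask * n), nrow = n_mask * n)
  for (j in seq_len(p)) {
    on <- rep(masks[, j], times = n)
    big[on, j] <- rep(X[, j], each = n_mask)[on]
  }
  v <- matrix(f(big), nrow = n_mask)  # coalition value x subject
  sizes <- rowSums(masks)
  # weight of coalition S when feature j is added to it; the full coalition
  # never serves as an S, so its weight slot is unused
  w <- ifelse(sizes < p, factorial(sizes) * factorial(pmax(p - sizes - 1, 0)) / factorial(p), 0)
  phi <- matrix(0, n, p, dimnames = dimnames(X))
  # index of S union {j}: masks are in binary counting order, bit j has
  # stride 2^(j-1)
  stride <- 2^(seq_len(p) - 1)
  for (j in seq_len(p)) {
    without <- which(!masks[, j])
    with_j <- without + stride[j]
    wj <- w[without]
    phi[, j] <- colSums(wj * (v[with_j, , drop = FALSE] - v[without, , drop = FALSE]))
  }
  phi
}

#' Sampled Shapley values by antithetic permutation sampling
#'
#' Monte-Carlo estimator for larger feature sets (up to ~20 features in the
#' hybrid-selection models, where `2^p` enumeration is infeasible): features
#' are added in random order and marginal probability gains are averaged
#' over permutations. Half the permutations are the reverses of the other
#' half (antithetic pairs), and every permutation's contributions telescope,
#' so efficiency holds exactly for the estimate.
#'
#' @inheritParams shapley_exact
#' @param n_perm Number of permutations (default 256, reverses included).
#' @param seed Integer seed for the permutation draw.
#' @return Matrix of Shapley values, same shape and dimnames as `X`.
#' @export
shapley_sampled <- function(model, X, background = NULL, n_perm = 256L,
                            seed = 1L) {
  f <- if (is.function(model)) model else function(M) predict_prob(model, M)
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(background)) background <- colMeans(X)
  half <- max(1L, n_perm %/% 2L)
  perms <- with_seed(seed, replicate(half, sample.int(p), simplify = FALSE))
  perms <- c(perms, lapply(perms, rev))
  phi <- matrix(0, n, p, dimnames = dimnames(X))
  bg_mat <- matrix(rep(background, each = n), nrow = n)
  for (perm in perms) {
    # stack the p + 1 prefix coalitions of this permutation and predict once
    blocks <- vector("list", p + 1)
    cur <- bg_mat
    blocks[[1]] <- cur
    for (k in seq_len(p)) {
      cur[, perm[k]] <- X[, perm[k]]
      blocks[[k + 1]] <- cur
    }
    v <- matrix(f(do.call(rbind, blocks)), nrow = n)  # subject x prefix size
    for (k in seq_len(p)) {
      phi[, perm[k]] <- phi[, perm[k]] + (v[, k + 1] - v[, k])
    }
  }
  phi / length(perms)
}
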