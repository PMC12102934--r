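# Mutual-information machinery shared by screening (CFFS) and the candidate
# measures (AHFS). Continuous features are discretized into equal-frequency
# bins; MI is the plug-in estimate in nats.

#' Equal-frequency discretization
#'
#' Bins a numeric vector at its empirical quantiles. Ties can collapse bin
#' edges, in which case fewer bins are produced; a constant vector yields a
#' single bin.
#'
#' @param x Numeric vector.
#' @param bins Number of bins (default 4).
#' @return Integer codes in `1..bins`.
#' @export
discretize_ef <- function(x, bins = 4L) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        type = 7, names = FALSE, na.rm = TRUE))
  if (length(br) <= 2) return(rep(1L, length(x)))
  codes <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(codes)
}

# Plug-in MI (nats) between two integer-coded variables.
mi_discrete <- function(a, b) {
  a <- match(a, sort(unique(a)))
  b <- match(b, sort(unique(b)))
  na <- max(a)
  nb <- max(b)
  joint <- matrix(tabulate((a - 1L) * nb + b, na * nb),
                  na, nb, byrow = TRUE) / length(a)
  pa <- rowSums(joint)
  pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
}

#' Mutual information between a feature and the class label
#'
#' Plug-in estimate in nats after equal-frequency binning of the feature
#' (default 4 bins). A feature identical to a balanced binary label attains
#' `ln 2`.
#'
#' @param x Numeric feature.
#' @param y Class labels (any discrete coding).
#' @param bins Bins for `x`.
#' @return MI in nats (>= 0).
#' @export
mutual_information <- function(x, y, bins = 4L) {
  mi_discrete(discretize_ef(x, bins), y)
}

# Precomputed discretizations and pairwise statistic matrices for one
# feature table. All pairwise quantities are materialized up front so the
# greedy selection loop reduces to matrix lookups.
mi_context <- function(table, bins = 4L) {
  feats <- feature_names(table)
  p <- length(feats)
  codes <- lapply(table[feats], discretize_ef, bins = bins)
  y <- table$label
  rel <- vapply(codes, mi_discrete, numeric(1), b = y)
  X <- as.matrix(table[, feats])
  corr_y <- abs(suppressWarnings(cor(X, y))[, 1])
  corr_y[is.na(corr_y)] <- 0
  CM <- abs(suppressWarnings(cor(X)))
  CM[is.na(CM)] <- 1
  PMI <- matrix(0, p, p, dimnames = list(feats, feats))
  JMI <- matrix(0, p, p, dimnames = list(feats, feats))
  for (i in seq_len(p - 1)) {
    ci <- codes[[i]]
    for (j in (i + 1):p) {
      PMI[i, j] <- PMI[j, i] <- mi_discrete(ci, codes[[j]])
      jm <- mi_discrete((ci - 1L) * bins + codes[[j]], y)
      JMI[i, j] <- JMI[j, i] <- jm
    }
  }
  list(features = feats, codes = codes, y = y, relevance = rel,
       corr_y = corr_y, pair_mi = PMI, joint_mi = JMI, pair_cor = CM,
       bins = bins)
}

# I((f, s); y): MI between the joint discretized pair and the label.
ctx_joint_mi <- function(ctx, f, s) ctx$joint_mi[f, s]

#' Score remaining features under one selection measure
#'
#' Standard forward-selection criteria scored against an already-selected
#' set `S` (empty `S` reduces every measure to its relevance term):
#' * `MIM`: `I(f; y)`
#' * `mRMR`: `I(f; y) - mean_{s in S} I(f; s)`
#' * `JMI`: `sum_{s in S} I((f, s); y)`
#' * `MMIFS`: `I(f; y) - beta * sum_{s in S} I(f; s)`
#' * `LCFS`: `|cor(f, y)| - mean_{s in S} |cor(f, s)|`
#'
#' @param ctx Internal context from `mi_context()`.
#' @param measure Measure name.
#' @param selected Character vector of already-selected features.
#' @param remaining Character vector of features to score.
#' @param beta Redundancy weight for MMIFS (default 0.5).
#' @return Named numeric scores over `remaining`.
#' @keywords internal
measure_scores <- function(ctx, measure, selected, remaining, beta = 0.5) {
  if (length(selected) == 0) {
    base <- if (measure == "LCFS") ctx$corr_y else ctx$relevance
    return(base[remaining])
  }
  sc <- switch(measure,
    MIM = ctx$relevance[remaining],
    mRMR = ctx$relevance[remaining] -
      rowMeans(ctx$pair_mi[remaining, selected, drop = FALSE]),
    JMI = rowSums(ctx$joint_mi[remaining, selected, drop = FALSE]),
    MMIFS = ctx$relevance[remaining] -
      beta * rowSums(ctx$pair_mi[remaining, selected, drop = FALSE]),
    LCFS = ctx$corr_y[remaining] -
      rowMeans(ctx$pair_cor[remaining, selected, drop = FALSE]),
    abort(paste0("unknown measure: ", measure))
  )
  setNames(as.numeric(sc), remaining)
}
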