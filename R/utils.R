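# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with one or more integer stream identifiers so that
#' independent random streams (subjects, runs, folds) can be seeded from a
#' single user-facing seed. The result is always a valid 32-bit seed.
#'
#' @param seed Master integer seed.
#' @param ... Integer stream identifiers.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) {
    # 32-bit multiplicative mix kept in double precision (exact below 2^53)
    h <- (h * 69069 + (as.numeric(v) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded internals do not
#' perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Population standard deviation.
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Maximal runs of a logical vector as a tibble (start, length, value),
# 1-based start indices.
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  tibble::tibble(
    start = ends - r$lengths + 1L,
    length = r$lengths,
    value = r$values
  )
}
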