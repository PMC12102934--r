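# Independent brute-force oracles. These deliberately re-derive results by
# the most literal method available (full rescans, nested loops, subset
# enumeration) so they share no code path with the implementation.

# Fixed point of short-run flipping, recomputed naively: rescan the whole
# binary vector each round, locate every maximal interior run by position,
# flip the shortest (earliest on ties), repeat.
oracle_flip <- function(state, min_len) {
  repeat {
    n <- length(state)
    starts <- c(1, which(diff(state) != 0) + 1)
    ends <- c(starts[-1] - 1, n)
    lens <- ends - starts + 1
    interior <- which(starts > 1 & ends < n)
    short <- interior[lens[interior] < min_len]
    if (length(short) == 0) return(state)
    pick <- short[which.min(lens[short])]
    state[starts[pick]:ends[pick]] <- !state[starts[pick]]
  }
}

# Peaks of a night by a literal element-walk.
oracle_peaks <- function(counts) {
  peaks <- list()
  i <- 1
  while (i <= length(counts)) {
    if (counts[i] > 0) {
      j <- i
      while (j < length(counts) && counts[j + 1] > 0) j <- j + 1
      peaks[[length(peaks) + 1]] <-
        list(start = i, length = j - i + 1, amplitude = max(counts[i:j]))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  peaks
}

# Per-night peak feature values by nested loops over categories, metrics and
# summary functions, mirroring the written grammar rather than the code.
oracle_night_features <- function(counts, close_gap_max = 2) {
  pk <- oracle_peaks(counts)
  amps <- vapply(pk, `[[`, numeric(1), "amplitude")
  classify <- function(idx) lapply(idx, function(i) pk[[i]])
  sets <- list(p_ = pk)
  if (length(pk)) {
    m <- median(amps)
    q <- quantile(amps, c(0.25, 0.75), type = 7, names = FALSE)
    sets$sp_ <- classify(which(amps <= m))
    sets$lp_ <- classify(which(amps > m))
    sets$sp_q_ <- classify(which(amps <= q[1]))
    sets$lp_q_ <- classify(which(amps >= q[2]))
  } else {
    sets$sp_ <- sets$lp_ <- sets$sp_q_ <- sets$lp_q_ <- list()
  }
  funcs <- list(avg = mean, std = function(v) sqrt(mean((v - mean(v))^2)),
                max = max, min = min, med = median)
  out <- c()
  for (cat in names(sets)) {
    ps <- sets[[cat]]
    a <- vapply(ps, `[[`, numeric(1), "amplitude")
    l <- vapply(ps, `[[`, numeric(1), "length")
    d <- numeric()
    if (length(ps) >= 2) {
      for (i in 1:(length(ps) - 1)) {
        d <- c(d, ps[[i + 1]]$start - (ps[[i]]$start + ps[[i]]$length))
      }
    }
    for (metric in c("a", "l", "d")) {
      v <- switch(metric, a = a, l = l, d = d)
      for (fn in names(funcs)) {
        out[paste0(cat, metric, "_", fn)] <-
          if (length(v)) funcs[[fn]](v) else NA_real_
      }
    }
    out[paste0(cat, "nbr")] <- length(ps)
    out[paste0(cat, "cls_nbr")] <- if (length(d)) sum(d <= close_gap_max) else 0
  }
  out
}

# All cliques of a small graph by exhaustive subset enumeration over an
# adjacency matrix; returns maximal cliques with size in [size_min, size_max],
# each as a sorted character vector, sorted lexicographically.
oracle_cliques <- function(adj, size_min = 3, size_max = 6) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  is_clique <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    pairs <- combn(idx, 2)
    all(adj[cbind(pairs[1, ], pairs[2, ])])
  }
  all_cliques <- list()
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (is_clique(idx)) all_cliques[[length(all_cliques) + 1]] <- idx
  }
  keys <- vapply(all_cliques, paste, "", collapse = ",")
  maximal <- vapply(all_cliques, function(idx) {
    ext <- setdiff(seq_len(n), idx)
    !any(vapply(ext, function(v) all(adj[v, idx]), logical(1)))
  }, logical(1))
  keep <- maximal & lengths(all_cliques) >= size_min & lengths(all_cliques) <= size_max
  out <- lapply(all_cliques[keep], function(idx) sort(nodes[idx]))
  out[order(vapply(out, paste, "", collapse = "\r"))]
}
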