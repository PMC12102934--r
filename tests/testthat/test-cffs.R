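test_that("screening keeps a perfectly separating feature and rejects nulls at ~alpha", {
  set.seed(91)
  n <- 50
  y <- rep(c(0L, 1L), each = n / 2)
  tbl <- dplyr::bind_cols(
    tibble::tibble(subject_id = as.character(1:n), label = y),
    tibble::tibble(perfect = as.numeric(y), null = rnorm(n))
  )
  class(tbl) <- c("feature_table", class(tbl))
  st <- screen_features(tbl)
  expect_true(st$keep[st$feature == "perfect"])
  expect_gt(st$mi[st$feature == "perfect"], 0.69)
  expect_lt(st$welch_p[st$feature == "perfect"], 1e-10)

  # null simulation: an independent feature passes in at most ~alpha cases
  kept <- vapply(1:400, function(i) {
    x <- rnorm(n)
    p <- t.test(x[y == 0], x[y == 1], var.equal = FALSE)$p.value
    p < 0.05 && mutual_information(x, y) >= 0.02
  }, logical(1))
  expect_lt(mean(kept), 0.10)
})

test_that("Welch arm matches the closed-form t statistic", {
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = FALSE)
  expect_equal(abs(unname(tt$statistic)), 3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_lt(tt$p.value, 0.05)
})

test_that("the feature graph links only weakly correlated pairs", {
  set.seed(92)
  n <- 200
  a <- rnorm(n)
  tbl <- dplyr::bind_cols(
    tibble::tibble(subject_id = as.character(1:n),
                   label = rep(c(0L, 1L), n / 2)),
    tibble::tibble(a = a, a2 = 2 * a + 1, b = rnorm(n), const = 1)
  )
  class(tbl) <- c("feature_table", class(tbl))
  g <- build_feature_graph(tbl, c("a", "a2", "b", "const"), corr_max = 0.25)
  am <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  expect_equal(am["a", "a2"], 0)      # perfectly correlated: no edge
  expect_equal(am["a", "b"], 1)       # independent: edge
  expect_equal(sum(am["const", ]), 0) # zero variance: isolated

  r <- cor(cbind(a, 2 * a + 1, rnorm(n)))
  expect_true(all(abs(r[upper.tri(r)][1]) > 0.25))
})

test_that("clique enumeration matches exhaustive subset search on known graphs", {
  k4 <- matrix(TRUE, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(k4) <- FALSE
  g4 <- igraph::graph_from_adjacency_matrix(k4, mode = "undirected")
  cl4 <- enumerate_cliques(g4)
  expect_equal(cl4, list(letters[1:4]))

  k4m <- k4
  k4m["a", "b"] <- k4m["b", "a"] <- FALSE
  gm <- igraph::graph_from_adjacency_matrix(k4m, mode = "undirected")
  expect_equal(enumerate_cliques(gm), list(c("a", "c", "d"), c("b", "c", "d")))
  expect_equal(enumerate_cliques(gm), oracle_cliques(k4m))

  empty <- matrix(FALSE, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  ge <- igraph::graph_from_adjacency_matrix(empty, mode = "undirected")
  expect_equal(enumerate_cliques(ge), list())
})

test_that("clique training is accurate on separable data and additive in SHAP", {
  tbl <- make_toy_table(12, 2, shift = 8, seed = 93)
  r <- train_clique(tbl, c("f1", "f2"), "LR", seed = 3)
  expect_equal(r$cv_accuracy, 1.0)

  X <- as.matrix(tbl[, c("f1", "f2")])
  fx <- actishap:::predict_prob(r$model, X)
  f_bg <- actishap:::predict_prob(r$model, matrix(colMeans(X), 1))
  expect_lt(max(abs(rowSums(r$shap) - (fx - f_bg))), 1e-6)
})

test_that("label-shuffled cliques score at chance accuracy", {
  set.seed(94)
  accs <- vapply(1:60, function(i) {
    tbl <- make_toy_table(12, 3, shift = 0, seed = 1000 + i)
    train_clique(tbl, c("f1", "f2", "f3"), "LR", seed = i)$cv_accuracy
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.02)
})

test_that("the accuracy gate is boundary inclusive", {
  fake <- function(a) structure(list(cv_accuracy = a), class = "cffs_model")
  kept <- filter_models(list(fake(0.55), fake(0.60), fake(0.71)))
  expect_equal(vapply(kept, `[[`, numeric(1), "cv_accuracy"), c(0.60, 0.71))
  expect_length(filter_models(list(fake(0.3), fake(0.59))), 0)
})

test_that("SHAP pooling conserves pair counts across models", {
  tbl <- make_toy_table(10, 3, shift = 2, seed = 95)
  m1 <- train_clique(tbl, c("f1", "f2"), "LR", seed = 1)
  m2 <- train_clique(tbl, c("f1", "f3"), "LR", seed = 2)
  agg1 <- aggregate_shap(list(m1), tbl)
  expect_equal(nrow(agg1$pooled), 2 * nrow(tbl))
  expect_equal(sort(unique(agg1$pooled$feature)), c("f1", "f2"))

  agg2 <- aggregate_shap(list(m1, m2), tbl)
  n_f1 <- sum(agg2$pooled$feature == "f1")
  expect_equal(n_f1, 2 * nrow(tbl))
  expect_equal(agg2$ranking$n_pooled[agg2$ranking$feature == "f1"], 2 * nrow(tbl))
})

test_that("the full clique pipeline retains only gate-passing models on valid cliques", {
  ft <- cached_features("psf_like", 1)
  res <- cached_cffs("psf_like", 1)
  expect_gt(length(res$retained), 0)
  accs <- vapply(res$retained, `[[`, numeric(1), "cv_accuracy")
  expect_true(all(accs >= 0.60))

  # every trained clique is mutually weakly correlated on the table
  X <- as.matrix(ft[, res$screened])
  for (cl in res$cliques[seq_len(min(25, length(res$cliques)))]) {
    r <- cor(X[, cl])
    expect_true(all(abs(r[upper.tri(r)]) <= 0.5 + 1e-12))
  }

  expect_equal(glance(res)$n_models, length(res$results))
  expect_identical(tidy(res)$feature, res$ranking$feature)
})

test_that("a fixed master seed reproduces the ranking file byte-identically", {
  tbl <- make_toy_table(16, 6, shift = 1.2, seed = 96)
  r1 <- run_cffs(tbl, corr_max = 0.5, seed = 7)
  r2 <- run_cffs(tbl, corr_max = 0.5, seed = 7)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_ranking_csv(r1, f1)
  write_ranking_csv(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
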