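# Small fixtures built in code, plus a cache so the expensive full-size
# cohorts used by the acceptance checks are extracted once per test run.

# Two-class Gaussian feature table for model-level tests.
make_toy_table <- function(n_per_class = 15, p = 4, shift = 0, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c(0L, 1L), each = n_per_class)
  X <- matrix(rnorm(n * p), n, p)
  X[y == 1, 1] <- X[y == 1, 1] + shift
  colnames(X) <- paste0("f", seq_len(p))
  tbl <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%02d", seq_len(n)), label = y),
    tibble::as_tibble(X)
  )
  class(tbl) <- c("feature_table", class(tbl))
  tbl
}

.fixture_cache <- new.env(parent = emptyenv())

# Imputed feature table of a full-size synthetic cohort (25/22, default
# profile), computed once per (effect, seed).
cached_features <- function(effect_name, seed) {
  key <- paste(effect_name, seed, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    coh <- generate_cohort(25, 22, subject_profile(),
                           effect_preset(effect_name), seed = seed)
    .fixture_cache[[key]] <- impute_features(extract_features(coh))
  }
  .fixture_cache[[key]]
}

# Full default-configuration pipeline runs on cached cohorts, shared across
# test files so each (framework, effect, seed) is trained once per suite run.
cached_cffs <- function(effect_name, seed) {
  key <- paste("cffs", effect_name, seed, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- run_cffs(cached_features(effect_name, seed),
                                      seed = seed)
  }
  .fixture_cache[[key]]
}

cached_ahfs <- function(effect_name, seed) {
  key <- paste("ahfs", effect_name, seed, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- run_ahfs(cached_features(effect_name, seed),
                                      seed = seed)
  }
  .fixture_cache[[key]]
}

# Family of a feature name for recovery bookkeeping: peak features map to
# <category><metric> (e.g. sp_l, lp_q_d), counts to <category>nbr, others to
# themselves.
feature_family <- function(f) {
  m <- regmatches(f, regexec("^(p|sp|lp|sp_q|lp_q)_(a|l|d|cls|first|last|nbr)", f))[[1]]
  if (length(m)) paste(m[2], m[3], sep = "_") else f
}

is_sp_l_family <- function(f) grepl("^sp(_q)?_l_", f)
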