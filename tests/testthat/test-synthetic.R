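test_that("generation is seed-deterministic and non-negative", {
  prof <- subject_profile(days = 3)
  a <- generate_subject(prof, seed = 42)
  b <- generate_subject(prof, seed = 42)
  expect_identical(a$count, b$count)
  expect_true(all(a$count >= 0))
  expect_equal(nrow(a), 3 * 1440)

  c2 <- generate_subject(prof, seed = 43)
  expect_false(identical(a$count, c2$count))
})

test_that("zero peak rate leaves sleep blocks silent", {
  prof <- subject_profile(days = 4, peak_rate = 0)
  es <- generate_subject(prof, seed = 7)
  iv <- filter_valid_sleep(detect_sleep(es))
  expect_gt(nrow(iv), 0)
  # detected intervals may absorb a few low-count epochs at the sleep/wake
  # transitions (that is the flipping's job); the block interior is silent
  margin <- 40
  for (sl in night_slices(es, iv)) {
    if (length(sl$counts) > 2 * margin) {
      core <- sl$counts[(margin + 1):(length(sl$counts) - margin)]
      expect_true(all(core == 0))
    }
  }
})

test_that("halving daytime amplitude halves mean daily activity", {
  prof <- subject_profile(days = 4)
  ratios <- vapply(1:30, function(i) {
    base <- generate_subject(prof, group_effect(), seed = 2000 + i)
    dimmed <- generate_subject(prof, group_effect(day_amp_mult = 0.5),
                               seed = 2000 + i)
    mean(dimmed$count) / mean(base$count)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.5), 0.06)
})

test_that("cohorts have the requested arm sizes and labels", {
  coh <- generate_cohort(25, 22, subject_profile(days = 2), seed = 5)
  expect_length(coh$series, 47)
  expect_equal(sum(coh$labels$label == 0), 25)
  expect_equal(sum(coh$labels$label == 1), 22)
  expect_identical(names(coh$series), coh$labels$subject_id)
})

test_that("nightly sleep blocks are detected as one interval nearly always", {
  prof <- subject_profile(days = 6)
  n_nights <- 0
  n_clean <- 0
  for (i in 1:12) {
    es <- generate_subject(prof, seed = 3000 + i)
    iv <- filter_valid_sleep(detect_sleep(es))
    # interior nights: intervals fully inside the record
    interior <- iv[iv$start_epoch > 1 & iv$end_epoch <= nrow(es), ]
    long_ones <- interior[interior$duration_min >= 180, ]
    expected <- prof$days - 1
    n_nights <- n_nights + expected
    # one long bout per interior night; every split or merged night is a miss
    n_clean <- n_clean + max(0, expected - abs(nrow(long_ones) - expected))
  }
  expect_gte(n_clean / n_nights, 0.95)
})

test_that("group-effect presets shift the intended features in direction", {
  prof <- subject_profile(days = 5)
  arm_means <- function(effect, col_fun, n = 25) {
    vapply(1:n, function(i) {
      es <- generate_subject(prof, effect, seed = 4000 + i)
      col_fun(es)
    }, numeric(1))
  }
  # chronic-illness-like: daytime activity down, rhythm regularity (IS) up
  base_adat <- arm_means(group_effect(), function(es) mean(es$count))
  cs_adat <- arm_means(effect_preset("cs_like"), function(es) mean(es$count))
  expect_lt(mean(cs_adat), mean(base_adat))

  base_is <- arm_means(group_effect(), interdaily_stability)
  cs_is <- arm_means(effect_preset("cs_like"), interdaily_stability)
  expect_gt(mean(cs_is), mean(base_is))

  base_m10 <- arm_means(group_effect(), function(es) m10_l5_ra_adat(es)$M10)
  cs_m10 <- arm_means(effect_preset("cs_like"), function(es) m10_l5_ra_adat(es)$M10)
  expect_lt(mean(cs_m10), mean(base_m10))

  # schizotypy-like: small-peak lengths up, large-peak density down
  sp_stat <- function(es, col) {
    iv <- filter_valid_sleep(detect_sleep(es))
    pf <- peak_features(night_slices(es, iv))
    pf[[col]]
  }
  base_spl <- arm_means(group_effect(), function(es) sp_stat(es, "sp_l_avg"))
  psf_spl <- arm_means(effect_preset("psf_like"), function(es) sp_stat(es, "sp_l_avg"))
  expect_gt(mean(psf_spl, na.rm = TRUE), mean(base_spl, na.rm = TRUE))

  base_lpn <- arm_means(group_effect(), function(es) sp_stat(es, "lp_nbr"))
  psf_lpn <- arm_means(effect_preset("psf_like"), function(es) sp_stat(es, "lp_nbr"))
  expect_lt(mean(psf_lpn, na.rm = TRUE), mean(base_lpn, na.rm = TRUE))
})

test_that("an identity effect leaves screening at the null rate", {
  # correlated features make the per-cohort kept count noisy; average the
  # rate over ten null cohorts
  rates <- vapply(1:10, function(s) {
    mean(screen_features(cached_features("identity", s))$keep)
  }, numeric(1))
  expect_lte(mean(rates), 0.10)
})

test_that("the planted small-peak effect is detectable by Welch at cohort size", {
  hits <- vapply(1:4, function(s) {
    ft <- cached_features("psf_like", s)
    st <- screen_features(ft)
    any(st$keep[grepl("^sp(_q)?_l_", st$feature)])
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})
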