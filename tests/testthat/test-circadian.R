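test_that("M10/L5/RA/ADAT match closed forms on simple profiles", {
  # activity 100 for a 10-hour block, zero elsewhere
  counts <- rep(0, 1440)
  counts[481:1080] <- 100
  r <- m10_l5_ra_adat(epoch_series(counts))
  expect_equal(r$M10, 100)
  expect_equal(r$L5, 0)
  expect_equal(r$RA, 1)
  expect_equal(r$ADAT, 100 * 10 / 24)

  rc <- m10_l5_ra_adat(epoch_series(rep(7, 1440)))
  expect_equal(rc$M10, 7)
  expect_equal(rc$L5, 7)
  expect_equal(rc$ADAT, 7)
  expect_equal(rc$RA, 0)
})

test_that("M10/L5 equal the exhaustive window scan on a noisy day", {
  set.seed(31)
  counts <- pmax(0, 100 * sin(2 * pi * (1:1440) / 1440) + rnorm(1440, 50, 20))
  r <- m10_l5_ra_adat(epoch_series(counts))
  w_means <- function(w) {
    vapply(1:(1440 - w + 1), function(s) mean(counts[s:(s + w - 1)]), numeric(1))
  }
  expect_equal(r$M10, max(w_means(600)), tolerance = 1e-12)
  expect_equal(r$L5, min(w_means(300)), tolerance = 1e-12)
})

test_that("interdaily stability is 1 for perfect periodicity and ~1/d for noise", {
  set.seed(32)
  prof <- rpois(1440, 30)
  es <- epoch_series(rep(prof, 4))
  expect_equal(interdaily_stability(es), 1)

  expect_true(is.na(interdaily_stability(epoch_series(rep(5, 2 * 1440)))))

  # i.i.d. noise over 8 days: E[IS] ~= 1/8; Monte Carlo against 3 SE
  sims <- vapply(1:200, function(i) {
    interdaily_stability(epoch_series(rnorm(8 * 1440, 100, 10)))
  }, numeric(1))
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - 1 / 8), 3 * se)
})

test_that("intradaily variability hits its closed forms", {
  expect_equal(intradaily_variability(epoch_series(rep(c(0, 1), 100))), 4)
  # ramp 0,1,2: IV = 3*2 / (2*2)
  expect_equal(intradaily_variability(epoch_series(c(0, 1, 2))), 1.5)
  expect_true(is.na(intradaily_variability(epoch_series(rep(3, 10)))))
})

test_that("global statistics use the population SD and count zeros", {
  g <- global_stats(epoch_series(c(0, 0, 2, 2)))
  expect_equal(g$activity_mean, 1)
  expect_equal(g$activity_std, 1)
  expect_equal(g$zero_ratio, 0.5)

  g0 <- global_stats(epoch_series(rep(0, 10)))
  expect_equal(unlist(g0), c(activity_mean = 0, activity_std = 0, zero_ratio = 1))

  set.seed(33)
  x <- rpois(500, 3)
  g2 <- global_stats(epoch_series(x))
  expect_equal(g2$activity_mean, mean(x))
  expect_equal(g2$activity_std, sqrt(mean((x - mean(x))^2)))
  expect_equal(g2$zero_ratio, mean(x == 0))
})

test_that("fragmentation index counts movement plus short immobile gaps", {
  expect_equal(fragmentation_index(rep(0, 100)), 0)
  expect_equal(fragmentation_index(rpois(100, 3) + 1), 1)
  # 3 mobile epochs + one zero-run of length 2 counted, length-3 run not
  expect_equal(fragmentation_index(c(5, 0, 0, 3, 0, 0, 0, 2), 2), 5 / 8)
})

test_that("circadian metrics stay in range and are scale invariant", {
  set.seed(34)
  for (i in 1:40) {
    counts <- rpois(2 * 1440, runif(1, 1, 50)) *
      rbinom(2 * 1440, 1, runif(1, 0.5, 1))
    es <- epoch_series(counts)
    is_v <- interdaily_stability(es)
    iv_v <- intradaily_variability(es)
    if (!is.na(is_v)) expect_true(is_v >= 0 && is_v <= 1)
    if (!is.na(iv_v)) expect_true(iv_v >= 0 && iv_v <= 4)
    fi <- fragmentation_index(counts[1:200] )
    expect_true(fi >= 0 && fi <= 1)

    c_pos <- counts + 1
    esp <- epoch_series(c_pos)
    ess <- epoch_series(3.7 * c_pos)
    expect_equal(m10_l5_ra_adat(esp)$RA, m10_l5_ra_adat(ess)$RA)
    expect_equal(interdaily_stability(esp), interdaily_stability(ess))
    expect_equal(intradaily_variability(esp), intradaily_variability(ess))
    expect_equal(global_stats(esp)$zero_ratio, global_stats(ess)$zero_ratio)
  }
})

test_that("IS/IV/M10/L5 agree with an independent literal implementation", {
  ref_is <- function(x, p = 1440) {
    n <- length(x)
    d <- n / p
    xm <- mean(x)
    prof <- vapply(1:p, function(h) mean(x[h + p * (0:(d - 1))]), numeric(1))
    (n * sum((prof - xm)^2)) / (p * sum((x - xm)^2))
  }
  ref_iv <- function(x) {
    n <- length(x)
    num <- 0
    for (i in 2:n) num <- num + (x[i] - x[i - 1])^2
    (n * num) / ((n - 1) * sum((x - mean(x))^2))
  }
  set.seed(35)
  for (i in 1:5) {
    x <- rpois(3 * 1440, 20) + rep(12 + sin(2 * pi * (1:1440) / 1440) * 10, 3)
    es <- epoch_series(x)
    expect_equal(interdaily_stability(es), ref_is(x), tolerance = 1e-9)
    expect_equal(intradaily_variability(es), ref_iv(x), tolerance = 1e-9)
  }
})
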