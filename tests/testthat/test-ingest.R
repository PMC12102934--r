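test_that("epoch CSV reading returns counts verbatim and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,timestamp,count",
               "S1,2020-01-01T00:00:00,0",
               "S1,2020-01-01T00:01:00,5",
               "S1,2020-01-01T00:02:00,2"), f)
  es <- read_epoch_csv(f)
  expect_equal(es$count, c(0, 5, 2))
  expect_equal(es$subject_id[1], "S1")

  writeLines("subject_id,timestamp,count", f)
  expect_error(read_epoch_csv(f), "no epochs")

  writeLines(character(), f)
  expect_error(read_epoch_csv(f, dialect = "haukeland"), "no epochs")

  writeLines(c("subject_id,timestamp,count",
               "S1,2020-01-01T00:00:00,3",
               "S1,2020-01-01T00:01:00"), f)
  expect_error(read_epoch_csv(f), "line 3")

  writeLines(c("subject_id,timestamp,count",
               "S1,2020-01-01T00:00:00,-4"), f)
  expect_error(read_epoch_csv(f), "negative")

  writeLines(c("10", "0", "3.5"), f)
  es2 <- read_epoch_csv(f, dialect = "haukeland", subject_id = "H1")
  expect_equal(es2$count, c(10, 0, 3.5))
})

test_that("generic epoch CSV round-trips byte-identically", {
  set.seed(41)
  es <- epoch_series(round(rgamma(1440, 2, 0.02), 3), subject_id = "RT")
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_epoch_csv(es, f1)
  back <- read_epoch_csv(f1)
  expect_equal(back$count, es$count)
  write_epoch_csv(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("PIM epoching takes per-second maxima summed per minute", {
  # all-zero raw input stays zero through any band
  raw0 <- raw_triaxial(numeric(1200), numeric(1200), numeric(1200))
  expect_equal(pim_from_raw(raw0)$count, rep(0, 2))

  # each second holds a permutation of 0.1..1.0 on one axis: per-second max
  # is 1.0, so each minute sums to 60 (filter bypassed)
  set.seed(7)
  x <- as.vector(vapply(1:60, function(s) sample(seq(0.1, 1, 0.1)),
                        numeric(10)))
  raw <- raw_triaxial(x, numeric(600), numeric(600))
  expect_equal(pim_from_raw(raw, band = NULL)$count, 60)

  # brute-force oracle on an arbitrary seeded minute
  set.seed(8)
  x <- rexp(600)
  raw <- raw_triaxial(x, numeric(600), numeric(600))
  oracle <- sum(vapply(1:60, function(s) max(x[(10 * s - 9):(10 * s)]),
                       numeric(1)))
  expect_equal(pim_from_raw(raw, band = NULL)$count, oracle)

  # invariant to permuting samples within each second
  xp <- as.vector(vapply(1:60, function(s) sample(x[(10 * s - 9):(10 * s)]),
                         numeric(10)))
  rawp <- raw_triaxial(xp, numeric(600), numeric(600))
  expect_equal(pim_from_raw(rawp, band = NULL)$count,
               pim_from_raw(raw, band = NULL)$count)
})

test_that("PIM output length, scaling and error conditions follow the contract", {
  set.seed(9)
  n <- 10 * 150  # 150 s -> 2 whole epochs
  raw <- raw_triaxial(rnorm(n), rnorm(n), rnorm(n))
  es <- pim_from_raw(raw, band = NULL)
  expect_equal(nrow(es), 2)

  scaled <- raw_triaxial(3 * raw$x_g, 3 * raw$y_g, 3 * raw$z_g)
  expect_equal(pim_from_raw(scaled, band = NULL)$count, 3 * es$count)

  short <- raw_triaxial(rnorm(100), rnorm(100), rnorm(100))
  expect_error(pim_from_raw(short), "shorter than one full epoch")
  expect_error(
    pim_from_raw(raw, band = filter_spec(0.25, 6)),
    "twice the band"
  )
  expect_error(filter_spec(2, 1), "low_hz")
})

test_that("band-pass filtering attenuates DC and passes in-band motion", {
  t <- seq(0, 120, by = 0.1)[-1]
  still <- raw_triaxial(rep(1, length(t)), numeric(length(t)), numeric(length(t)))
  moving <- raw_triaxial(sin(2 * pi * 1 * t), numeric(length(t)),
                         numeric(length(t)))
  c_still <- pim_from_raw(still)$count
  c_moving <- pim_from_raw(moving)$count
  expect_lt(max(c_still), 1)        # DC blocked: counts near zero
  expect_gt(min(c_moving), 30)      # 1 Hz movement passes the 0.25-2.5 band
})

test_that("missing-day filtering removes exactly the all-zero days and is idempotent", {
  day <- function(x) rep(x, 1440)
  es <- epoch_series(c(day(5), day(0), day(3)))
  out <- drop_missing_days(es)
  expect_equal(max(out$day), 2)
  expect_equal(nrow(out), 2 * 1440)

  clean <- epoch_series(c(day(5), day(3)))
  expect_equal(drop_missing_days(clean)$count, clean$count)

  set.seed(10)
  counts <- as.vector(vapply(1:10, function(d) rpois(1440, 5) + 1, numeric(1440)))
  zero_days <- c(2, 5, 9)
  for (d in zero_days) counts[(d - 1) * 1440 + 1:1440] <- 0
  out2 <- drop_missing_days(epoch_series(counts))
  expect_equal(max(out2$day), 7)
  expect_equal(drop_missing_days(out2)$count, out2$count)

  expect_error(drop_missing_days(epoch_series(day(0))), "no valid days")
})

test_that("partial leading and trailing days are trimmed to whole days", {
  start <- as.POSIXct("2020-01-01 22:00:00", tz = "UTC")
  es <- epoch_series(rep(1, 120 + 1440 + 60), start_time = start)
  out <- trim_partial_days(es)
  expect_equal(nrow(out), 1440)
  expect_equal(unique(out$day), 1L)
})
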