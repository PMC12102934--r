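#' Synthetic subject profile
#'
#' Parameters of the generative model for one subject's multi-day actigraphy
#' record: a diurnal activity bump over the wake period with multiplicative
#' noise, and nightly sleep blocks at zero floor carrying sparse movement
#' peaks (Poisson arrivals, geometric lengths, gamma amplitudes).
#'
#' @param days Number of whole recording days (default 10).
#' @param day_amp Mean daytime activity at the diurnal peak, counts/min
#'   (default 250).
#' @param day_floor Daytime baseline outside the bump, counts/min (default 20).
#' @param night_floor Sleep-block baseline (default 0).
#' @param sleep_start_min Mean sleep onset, minutes after midnight of the
#'   preceding day (default 1380 = 23:00), with SD `sleep_start_sd` (30).
#' @param sleep_len_min Mean sleep duration in minutes (default 480), with SD
#'   `sleep_len_sd` (45).
#' @param peak_rate Nocturnal movement peaks per hour of sleep (default 6).
#' @param peak_len_mean Mean peak length in epochs (default 2).
#' @param peak_amp_mean Mean peak amplitude in counts (default 40).
#' @param circadian_noise_sd SD of the log-normal day-to-day amplitude jitter
#'   (default 0.2).
#' @param subject_sd SD of the log-normal between-subject heterogeneity
#'   applied to `day_amp`, `peak_rate`, `peak_len_mean` and `peak_amp_mean`
#'   (default 0.2). Without it every subject of an arm would share identical
#'   movement parameters and group effects would separate arms almost
#'   perfectly, which real cohorts do not.
#' @return A `subject_profile` list.
#' @export
subject_profile <- function(days = 10L, day_amp = 250, day_floor = 20,
                            night_floor = 0,
                            sleep_start_min = 1380, sleep_start_sd = 30,
                            sleep_len_min = 480, sleep_len_sd = 45,
                            peak_rate = 6, peak_len_mean = 2,
                            peak_amp_mean = 40, circadian_noise_sd = 0.2,
                            subject_sd = 0.2) {
  stopifnot(days >= 1, day_amp > 0, sleep_len_min < 900, peak_len_mean >= 1)
  structure(as.list(environment()), class = "subject_profile")
}

#' Group effect: multipliers on profile parameters
#'
#' Encodes how a phenotype group departs from the base profile. All
#' multipliers are positive; 1 means no effect.
#'
#' @param day_amp_mult Scales daytime activity (chronic-illness-like < 1).
#' @param small_peak_len_mult Scales the length of low-amplitude nocturnal
#'   peaks (schizotypy-like > 1).
#' @param large_peak_rate_mult Thins high-amplitude peaks (< 1 = sparser
#'   large movements).
#' @param peak_rate_mult Scales the overall peak arrival rate.
#' @param peak_amp_mult Scales peak amplitudes.
#' @param regularity_mult Scales day-to-day jitter SDs; < 1 makes the rhythm
#'   more regular (drives interdaily stability up).
#' @return A `group_effect` list.
#' @export
group_effect <- function(day_amp_mult = 1, small_peak_len_mult = 1,
                         large_peak_rate_mult = 1, peak_rate_mult = 1,
                         peak_amp_mult = 1, regularity_mult = 1) {
  vals <- as.list(environment())
  if (any(unlist(vals) <= 0)) abort("effect multipliers must be positive")
  structure(vals, class = "group_effect")
}

#' Named group-effect presets
#'
#' `"identity"` is the null effect. `"cs_like"` emulates a chronic-illness
#' movement phenotype: reduced daytime activity and a more regular rhythm.
#' `"psf_like"` emulates a positive-schizotypy-like sleep-movement phenotype:
#' longer low-amplitude nocturnal peaks (length x1.5) and sparser
#' high-amplitude peaks (rate x0.7).
#'
#' @param name One of `"identity"`, `"cs_like"`, `"psf_like"`.
#' @return A [group_effect()].
#' @export
effect_preset <- function(name = c("identity", "cs_like", "psf_like")) {
  name <- match.arg(name)
  switch(name,
    identity = group_effect(),
    cs_like = group_effect(day_amp_mult = 0.6, regularity_mult = 0.5,
                           peak_rate_mult = 0.7),
    psf_like = group_effect(small_peak_len_mult = 1.5,
                            large_peak_rate_mult = 0.7)
  )
}

#' Generate one synthetic subject
#'
#' Builds a `days`-day record starting at midnight. Wake epochs follow a
#' raised-sinusoid diurnal bump (07:00-23:00) over a daytime floor, with
#' day-level log-normal jitter and epoch-level gamma noise. Each night a
#' sleep block (normal onset/duration) is zeroed and seeded with movement
#' peaks: Poisson arrivals at `peak_rate`/h, geometric lengths, gamma
#' amplitudes (shape 2). Peaks below the amplitude-distribution median count
#' as "small" for `small_peak_len_mult`; those above are thinned by
#' `large_peak_rate_mult`. Fully determined by `seed`.
#'
#' @param profile A [subject_profile()].
#' @param effect A [group_effect()].
#' @param subject_id Subject identifier.
#' @param seed Integer seed.
#' @return An [epoch_series()] of `days * 1440` epochs.
#' @export
generate_subject <- function(profile, effect = group_effect(),
                             subject_id = "S1", seed = 1L) {
  p <- profile
  e <- effect
  n <- p$days * 1440L
  with_seed(seed, {
    # subject-level heterogeneity: who this subject is, before any group effect
    het <- exp(rnorm(4, 0, p$subject_sd))
    day_amp <- p$day_amp * het[1]
    peak_rate <- p$peak_rate * het[2]
    peak_len_mean <- p$peak_len_mean * het[3]
    peak_amp_mean <- p$peak_amp_mean * het[4]

    minute_of_day <- ((seq_len(n) - 1) %% 1440)
    bump <- pmax(0, sin(pi * (minute_of_day - 420) / 960))
    day_jit <- exp(rnorm(p$days, 0, p$circadian_noise_sd * e$regularity_mult))
    # the effect multiplier scales all waking activity, floor included
    base <- e$day_amp_mult *
      (p$day_floor + day_amp * day_jit[(seq_len(n) - 1) %/% 1440 + 1] * bump)
    counts <- base * rgamma(n, shape = 3, scale = 1 / 3)

    amp_scale <- peak_amp_mean * e$peak_amp_mult / 2
    amp_median <- stats::qgamma(0.5, shape = 2, scale = amp_scale)
    for (night in 0:p$days) {
      onset <- round((night - 1) * 1440 + p$sleep_start_min +
                       rnorm(1, 0, p$sleep_start_sd * e$regularity_mult))
      dur <- round(rnorm(1, p$sleep_len_min, p$sleep_len_sd * e$regularity_mult))
      dur <- max(60, dur)
      lo <- max(1, onset)
      hi <- min(n, onset + dur - 1)
      if (lo > hi) next
      counts[lo:hi] <- p$night_floor
      n_peaks <- rpois(1, dur / 60 * peak_rate * e$peak_rate_mult)
      if (n_peaks == 0) next
      amps <- rgamma(n_peaks, shape = 2, scale = amp_scale)
      small <- amps < amp_median
      keep <- small | (runif(n_peaks) < e$large_peak_rate_mult)
      for (j in which(keep)) {
        len_mean <- peak_len_mean * if (small[j]) e$small_peak_len_mult else 1
        len <- 1L + rgeom(1, prob = 1 / max(1, len_mean))
        s <- onset + floor(runif(1, 0, dur - len))
        # peaks of a truncated boundary night may fall outside the record
        if (s < lo || s + len - 1 > hi) next
        seg <- amps[j] * runif(len, 0.5, 1)
        seg[sample.int(len, 1)] <- amps[j]
        idx <- s:(s + len - 1)
        counts[idx] <- pmax(counts[idx], seg)
      }
    }
    epoch_series(pmax(counts, 0), subject_id = subject_id)
  })
}

#' Generate a labelled synthetic cohort
#'
#' Controls come from the base profile, cases from the base profile under the
#' group effect; per-subject seeds are derived from the cohort seed. Default
#' arm sizes (25 controls, 22 cases) mirror a typical small case-control
#' actigraphy study.
#'
#' @param n_control,n_case Arm sizes (default 25 and 22).
#' @param base_profile A [subject_profile()].
#' @param effect A [group_effect()] applied to cases only.
#' @param seed Cohort master seed.
#' @return An `acti_cohort` list with `series` (named list of
#'   [epoch_series()]) and `labels` (tibble `subject_id`, `label` with 0 =
#'   control, 1 = case).
#' @export
generate_cohort <- function(n_control = 25L, n_case = 22L,
                            base_profile = subject_profile(),
                            effect = group_effect(), seed = 1L) {
  stopifnot(n_control >= 2, n_case >= 2)
  ids <- c(sprintf("C%02d", seq_len(n_control)), sprintf("P%02d", seq_len(n_case)))
  labels <- c(rep(0L, n_control), rep(1L, n_case))
  series <- purrr::imap(setNames(labels, ids), function(lab, id) {
    generate_subject(base_profile,
                     effect = if (lab == 1) effect else group_effect(),
                     subject_id = id,
                     seed = derive_seed(seed, match(id, ids)))
  })
  structure(list(series = series,
                 labels = tibble::tibble(subject_id = ids, label = labels)),
            class = "acti_cohort")
}
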