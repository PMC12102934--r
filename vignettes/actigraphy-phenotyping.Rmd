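---
title: "Actigraphy phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Actigraphy phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`actishap` implements a complete analysis chain for wrist-actigraphy
case-control studies: epoch-level preprocessing, sleep detection, three
families of engineered features (circadian, nocturnal peak morphology,
wavelet structure), and two ensemble feature-selection frameworks that
attribute group separation to features through pooled Shapley values. This
vignette explains the models behind each stage, the tunable parameters and
their defaults, and the design decisions taken where the methodology left
genuine freedom. It states no empirical claims beyond what the package's
test suite and acceptance script compute.

## Data model

The carrier between stages is the **epoch series**: one subject's activity
counts at 1-minute epochs, laid out as a tibble (`subject_id`, `epoch`,
`day`, `count`). Days run midnight-to-midnight on the local clock; leading
and trailing partial days are trimmed (`trim_partial_days()`) so that
window-based metrics are comparable across subjects. Counts are
non-negative reals: devices that integrate filtered acceleration magnitudes
produce continuous counts, and the package never rounds them.

Two ingestion routes exist:

* **Pre-epoched counts** (`read_epoch_csv()`): counts are read verbatim,
  one per minute. Band-pass specifications reported for such devices (e.g.
  a 3–11 Hz hardware filter) are metadata only; the filtering already
  happened on the device.
* **Raw triaxial acceleration** (`pim_from_raw()`): 10 Hz x/y/z in g. Each
  axis is band-pass filtered (zero-phase Butterworth, default 0.25–2.5 Hz,
  order 4 applied forward–backward), combined into a per-sample Euclidean
  magnitude, reduced to per-second maxima, and the 60 maxima of each minute
  are summed — the proportional-integration-mode (PIM) counting scheme.
  The Euclidean norm before the per-second maximum is our choice (devices
  document "integration across the three axes" without a formula): it is
  orientation-invariant and standard practice. Whether the band-pass is
  applied per axis before the norm (default) or to the norm afterwards is
  configurable (`filter_first`), since period documentation is ambiguous;
  with the norm-first route the filtered magnitude is rectified because
  band-passing removes the DC level.

Whole days whose counts are all zero are removed
(`drop_missing_days()`) — long all-zero stretches mean the device was off
or off the wrist. Partial days are never excluded; missing data in this
modality affects full days.

## Sleep detection

`detect_sleep()` binarizes epochs at a low-activity threshold (default 10
counts/min) and then repairs the state sequence: any maximal run — rest or
wake — shorter than `min_segment_len` (default 30 epochs) is flipped to the
opposite state, iterating to a fixed point. Flips are applied shortest run
first with ties to the earlier run, which makes the fixed point
deterministic; the first and last runs of a record are exempt because their
true length is unknown (they are truncated by the recording window).
Maximal rest runs are returned as sleep intervals; an interval may span
midnight, and `night_id` numbers intervals rather than calendar days.

The threshold and minimum segment length have no published reference
values for this device class; the defaults were chosen so that the
synthetic cohort's nightly sleep blocks (7–9 h) are detected as single
intervals with 6–9 h modal duration, and both are exposed in
`sleep_params()`. No equivalence with any particular study's
parameterization is claimed. Sleep bouts longer than 15 h (900 epochs) are
treated as device malfunction and removed (`filter_valid_sleep()`).

## Feature engineering

### Circadian and global metrics

For each subject (`circadian_features()`):

* **M10 / L5** — the largest mean over consecutive 10-hour windows and the
  smallest mean over consecutive 5-hour windows within each day (no
  wrap-around), averaged across days. A `mean_profile` mode that scans the
  across-day average profile once is available.
* **RA** = (M10 − L5)/(M10 + L5), the relative amplitude in [0, 1]; an
  all-zero subject reports RA = 0.
* **ADAT** — the grand mean of all counts.
* **IS** (interdaily stability) = `N Σ_h (x̄_h − x̄)² / (p Σ_i (x_i − x̄)²)`,
  the classical variance-ratio form with the per-time-of-day means `x̄_h`.
  The profile resolution is selectable: `minute` (p = 1440, default —
  matching the 1-minute epoching) or the classical hourly variant (p = 24,
  computed on hourly bin means). IS is 1 for a perfectly repeated daily
  pattern and ≈ 1/d for white noise over d days.
* **IV** (intradaily variability) =
  `N Σ (x_i − x_{i−1})² / ((N−1) Σ (x_i − x̄)²)`, in [0, 4]; 4 is attained
  by a strictly alternating series.
* **activity_mean / activity_std / zero_ratio** — mean, *population*
  standard deviation, and fraction of zero epochs.
* **FI_m / FI_std** — mean/SD across nights of the sleep fragmentation
  index: the fraction of a sleep bout spent in movement, where movement is
  any positive epoch plus any zero-run of at most `short_immobile_max`
  epochs (default 2). Counting short immobile gaps by epochs (not by gap
  count) is a choice; the alternative convention exists in the literature
  and no equivalence is claimed.
* **slp_tm** — mean nightly sleep duration in minutes.

Metrics undefined for a subject (constant series, no valid nights)
propagate as `NA` and are median-imputed within group before modelling;
features missing in more than 20 % of subjects are dropped
(`impute_features()`).

### Nocturnal peak morphology

Daytime activity is dominated by idiosyncratic routine, so movement
*during sleep* is analyzed instead. Within each sleep bout, a **peak** is a
maximal run of positive counts; zeros separate peaks; amplitude is the
maximum count in the run (a mean-within-run variant sits behind a flag).
Peaks are classified two ways: by the night's **median** amplitude (ties to
"small", so an all-equal night is all small) and by **quartiles** (small
≤ Q1, large ≥ Q3, the middle half unclassified; quartiles are type-7
linear interpolation, stated because Q1/Q3 depend on the estimator).

For every category (`p_`, `sp_`, `lp_`, `sp_q_`, `lp_q_`) the per-night
metric vectors are amplitude (`a`), length (`l`) and distance (`d`) — the
end-to-start gap between consecutive peaks *of that category*, ignoring
interleaved peaks of other classes. Each vector is summarized per night by
`avg/std/max/min/med`, counts by `nbr` (peaks per night) and `cls_nbr`
(consecutive pairs closer than `close_gap_max`, default 2 epochs), and the
first/last peak of each night contributes its amplitude (`_a`) and start
offset (`_t`), summarized by mean and SD across nights. Per-night values
are averaged across nights, skipping nights on which a metric is undefined
(e.g. no large peaks). The name grammar `<category><metric>_<func>`
(`sp_l_avg`, `lp_q_d_med`, `p_first_a_avg`, …) is deterministic — 93
columns — which makes column-exact regression tests possible.

### Wavelet structure

The counts of all valid sleep bouts are concatenated chronologically and
transformed with a Morlet continuous wavelet transform (ω₀ = 6; 64
log-spaced scales spanning 1–200 epochs, i.e. 1 min to 200 min at 1-minute
epochs). The transform is evaluated in the frequency domain with the series
zero-padded to the next power of two. The coefficient magnitude is
normalized to [0, 1] — by the global map maximum by default, or per scale.

The **structure parameter** at a scale is the fraction of time points whose
normalized magnitude reaches `corr_threshold` (default 0.7): the occupancy
of prominent structure at that time resolution. `structure_pms` integrates
the per-scale parameter over the scale window by the trapezoid rule, and
`wavelet_fi` = 1 − mean per-scale parameter is a wavelet fragmentation
index. This occupancy definition reproduces the qualitative contract of the
approach — high coefficient-magnitude regions mark structured movement —
but the original's exact structure-parameter formula is not public, so *no
numerical equivalence with any published variant is claimed*; threshold,
normalization and window (including its unit) are configuration. The window
unit ambiguity (seconds vs minutes in different descriptions of this
technique) is resolved as minutes = epochs by default.

## Feature selection

Both frameworks consume a `feature_table` (subjects × named features plus a
binary label) and attribute their ensemble's behaviour through Shapley
values of the class-1 probability. The Shapley value function replaces
features outside the coalition by a single background reference — the
training-data feature means — so efficiency reads
`Σ_j φ_ij = f(x_i) − f(x̄)`.

### CFFS: clique-forming feature selection

1. **Screen**: keep features with Welch two-sample p < 0.05 *and* mutual
   information with the label ≥ `mi_min`. MI is a plug-in estimate after
   4-bin equal-frequency discretization, in nats. The default
   `mi_min = 0.05` was set above the plug-in estimator's bias
   (≈ (B−1)/(2n) ≈ 0.03 nats at B = 4 bins and n = 47): a floor below the
   bias never rejects anything and reduces screening to the Welch test
   alone. Screening generates model candidates rather than inferences, so
   no multiple-testing correction is applied.
2. **Graph**: vertices are screened features; an edge joins pairs with
   |Pearson r| ≤ `corr_max`. The default 0.5 (linked features share at most
   a quarter of their variance) reflects a structural fact: screened sets
   are dominated by a few latent factors, and with tighter thresholds the
   graph frequently contains *no* clique of three or more features,
   leaving the framework without a single candidate model. Zero-variance
   features are treated as fully correlated with everything.
3. **Cliques**: maximal cliques with size in [3, 6]
   (`enumerate_cliques()`; all-cliques-in-band via `expand_subcliques`).
   Clique counts vary steeply with the screened set's correlation
   structure; `run_cffs()` trains at most `max_cliques = 300` of them
   (a seeded uniform subsample when exceeded), the scale the framework is
   designed around.
4. **Models**: each clique is trained with ridge logistic regression
   (C = 1), random forest (200 trees) and a single-hidden-layer network
   (8 logistic units, weight decay 10⁻³, ≤ 500 iterations) under
   stratified 3-fold cross-validation, with standardization fitted on
   training folds only. Degenerate folds are redrawn (≤ 10 attempts).
   Models with CV accuracy ≥ 60 % (boundary inclusive) are retained.
5. **Attribution**: each retained model is refit on all subjects and
   explained with *exact* Shapley values by subset enumeration (≤ 6
   features ⇒ ≤ 64 coalitions). The per-feature (feature value, Shapley
   value) pairs are pooled across retained models and ranked by mean
   |Shapley|.

### AHFS: adaptive hybrid feature selection

A greedy forward selection arbitrated by a deliberately small network. At
each step five measures each propose their best-scoring remaining feature —
MIM `I(f;y)`; mRMR `I(f;y) − mean_{s∈S} I(f;s)`; JMI `Σ_{s∈S} I((f,s);y)`;
MMIFS `I(f;y) − β Σ I(f;s)` (β = 0.5); LCFS on correlation magnitudes —
and a 2-hidden-unit network (a larger evaluator overfits cohorts of this
size) is trained on `selected + candidate` under the same stratified CV;
the candidate with the highest mean accuracy wins, ties to the
alphabetically lower name. Twenty steps per run and twenty independent
runs give 400 selected-feature slots; each run's best-accuracy step is
refit and explained with *sampled* Shapley values (256 antithetic
permutations — exact enumeration is infeasible at up to 20 features;
permutation estimates telescope, so efficiency still holds exactly), and
the 20 best models are pooled exactly as in CFFS. Candidate evaluation
uses cross-validated accuracy rather than training error; this choice is
flagged rather than claimed original.

## The synthetic cohort generator

`generate_cohort()` builds the study conditions every stage is tested
under: by default 25 controls and 22 cases, 10 days each. A subject is a
diurnal raised-sinusoid activity bump (07:00–23:00, peak 250 counts/min
over a floor of 20) under day-level log-normal jitter (SD 0.2) and
epoch-level gamma noise, with a nightly sleep block (onset ≈ 23:00 SD 30
min, duration 480 SD 45 min) zeroed and seeded with movement peaks:
Poisson arrivals at 6/h, geometric lengths (mean 2 epochs), gamma
amplitudes (shape 2, mean 40). These are the simplest processes that
reproduce zero-separated nocturnal bursts; all are swappable behind the
profile interface.

Two realism points matter for interpreting test results:

* **Between-subject heterogeneity** (`subject_sd = 0.2`, log-normal on
  daytime amplitude, peak rate, peak length, peak amplitude). Without it
  every subject of an arm shares identical movement parameters, so any
  group effect separates arms almost perfectly — single features reach CV
  accuracy 1.0 and the 60 % gate retains everything, unlike real cohorts
  where accuracies spread over 0.6–0.9. The default keeps single-feature
  accuracies in that realistic range.
* **Group effects** are multipliers on profile parameters. The
  `psf_like` preset (small-peak length × 1.5, large-peak rate × 0.7)
  encodes a schizotypy-like sleep-movement phenotype: longer low-amplitude
  movements, sparser high-amplitude ones. `cs_like` (daytime amplitude
  × 0.6, day-to-day jitter × 0.5, peak rate × 0.7) encodes a
  chronic-illness-like phenotype: less daytime activity and a *more*
  regular rhythm (higher IS). At generation time a peak is "small" if its
  amplitude falls below the amplitude distribution's median — a generative
  proxy for the per-night median classification applied downstream.

What the generator does **not** emulate: device noise spectra, non-wear
artifacts other than whole missing days, naps, weekday/weekend structure,
demographic covariates, or medication effects. Passing recovery tests
therefore show that the pipeline can find planted sleep-movement effects
of realistic size at realistic cohort sizes — not that it reproduces any
clinical study's feature rankings.

## Numerical choices and degenerate inputs

* Ties at the small/large amplitude boundary go to "small"; ties in AHFS
  candidate accuracy go to the alphabetically lower feature name; the flip
  scheduler takes the shortest run, earliest on ties — all chosen for
  deterministic fixed points and byte-reproducible outputs.
* Constant features: Welch undefined ⇒ dropped at screening; in the graph
  they are isolated; as model inputs their standardization scale is set to
  1; their exact Shapley value is identically 0 (dummy axiom).
* All randomness flows from one master seed through a mixing function
  (`derive_seed()`), so cohorts, folds, network initializations, sampled
  permutations and clique subsamples are reproducible; rankings written by
  `write_ranking_csv()` are byte-identical across runs at a fixed seed.
* Suite problem sizes: the package's tests exercise full-size cohorts
  (47 subjects × 10 days, ~110 features) for the protocol and recovery
  checks — ten cohort seeds per arm — and reduced fixtures (4–6 day
  records, toy Gaussian tables) for unit-level properties. Oracle
  equivalence uses exhaustive enumeration up to the sizes where it is
  exact (all binary strings of length 10 for flipping plus 10 000 random
  strings to length 50; all subsets on graphs of ≤ 8 nodes).

## Known limitations

* The wavelet structure factor is an occupancy statistic calibrated to the
  qualitative behaviour of the published maps, not a numerical replica of
  the original (unpublished) definition.
* The clique-count distribution is heavy-tailed across cohorts; the
  `max_cliques` guardrail keeps runtime bounded at the cost of subsampling
  extremely dense graphs.
* MI estimates at n ≈ 50 with 4 bins carry O(1/n) bias; thresholds on MI
  should be read relative to that bias, not as information measurements.
* Sampled Shapley values carry Monte-Carlo error (±, roughly, 0.02 on the
  probability scale at 256 permutations); only the exact clique-model
  values satisfy the axioms to machine precision.
* The sleep detector is a movement-threshold method; it cannot separate
  quiet wakefulness from sleep and is not a polysomnography substitute.
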