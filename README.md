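# actishap

Digital phenotyping from wrist actigraphy for small case-control cohorts:
feature engineering over per-minute activity counts — circadian
rest-activity metrics, nocturnal movement-peak morphology, Morlet-wavelet
structure factors — and two ensemble feature-selection frameworks that rank
features by pooled Shapley values:

* **CFFS** (clique-forming feature selection): screen features by Welch's
  test and mutual information, connect weakly correlated pairs
  (|Pearson r| ≤ 0.5) into a graph, train every maximal clique of 3–6
  features with logistic regression, random forest and a small neural
  network under stratified 3-fold CV, keep models with accuracy ≥ 60 %,
  and pool exact (subset-enumeration) Shapley values across them.
* **AHFS** (adaptive hybrid feature selection): greedy forward selection
  where MIM, mRMR, JMI, MMIFS and LCFS each propose a candidate and a
  2-hidden-unit network arbitrates by CV accuracy; 20 runs × 20 steps
  yield 400 selected-feature slots and 20 best models whose sampled
  Shapley values (256 antithetic permutations) are pooled.

The intended users are researchers analyzing actigraphy from psychiatric
or sleep cohorts who need interpretable group-separating features at
n ≈ 50, not black-box classifiers.

The core rest-activity metrics follow the standard definitions, e.g.

    IS = N · Σ_h (x̄_h − x̄)² / ( p · Σ_i (x_i − x̄)² )        ∈ [0, 1]
    IV = N · Σ_{i≥2} (x_i − x_{i−1})² / ( (N−1) · Σ_i (x_i − x̄)² ) ∈ [0, 4]
    RA = (M10 − L5) / (M10 + L5)

and sleep is detected by a low-activity threshold with iterative flipping
of short rest/wake segments (see the methods vignette,
`vignettes/actigraphy-phenotyping.Rmd`, for every model and default).

A seeded synthetic cohort generator (`generate_cohort()`) emulates
multi-day count series — diurnal activity bump, nightly sleep blocks with
sparse movement peaks, between-subject heterogeneity — with injectable
group effects (`effect_preset("psf_like")`, `effect_preset("cs_like")`),
so the whole pipeline is testable without any data download.

## Worked example

```r
library(actishap)

# a 25-control / 22-case cohort with a schizotypy-like sleep-movement
# effect: small-peak length x1.5, large-peak rate x0.7
cohort   <- generate_cohort(25, 22, subject_profile(),
                            effect_preset("psf_like"), seed = 1)
features <- impute_features(extract_features(cohort))
dim(features)
#> [1]  47 109        # 47 subjects, 107 features + id and label

cffs <- run_cffs(features, seed = 1)
glance(cffs)
#> # A tibble: 1 x 5
#>   n_screened n_cliques n_models n_retained min_retained_accuracy
#>        <int>     <int>    <int>      <int>                 <dbl>
#> 1         44        92      276        229                 0.601

head(tidy(cffs), 5)
#> # A tibble: 5 x 4
#>    rank feature      mean_abs_shap n_pooled
#>   <int> <chr>                <dbl>    <int>
#> 1     1 sp_q_l_med           0.246      282
#> 2     2 sp_d_min             0.217     1739
#> 3     3 p_l_max              0.208      282
#> 4     4 p_last_t_avg         0.189     1128
#> 5     5 sp_d_med             0.184      846

ahfs <- run_ahfs(features, seed = 1)
glance(ahfs)
#> # A tibble: 1 x 4
#>   n_runs n_slots best_models mean_best_accuracy
#>    <int>   <int>       <int>              <dbl>
#> 1     20     400          20              0.901

autoplot(cffs)   # beeswarm-style SHAP summary of the pooled ranking
```

The ranking is led by nocturnal sleep-movement morphology: `sp_q_l_med`
(median length of low-amplitude peaks, the planted ×1.5 effect) ranks
first, with small-peak spacing (`sp_d_*`) and overall peak length
(`p_l_max`) following — the signature of longer small movements and
sparser large ones. `n_pooled` counts the (subject × model) Shapley pairs
behind each feature's rank, and `mean_abs_shap` is the mean absolute
pooled Shapley value on the class-probability scale. The 60 % accuracy
gate discards 47 of the 276 trained clique models here.

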