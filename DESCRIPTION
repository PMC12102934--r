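Package: actishap
Title: Actigraphy Phenotyping with Clique and Hybrid Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for digital phenotyping from wrist actigraphy: ingestion of
    per-minute activity-count series and raw triaxial acceleration (PIM
    epoching), threshold-based sleep detection with short-segment flipping,
    rest-activity rhythm metrics (M10, L5, RA, ADAT, IS, IV), nocturnal
    peak-morphology features, Morlet continuous-wavelet structure factors, and
    two ensemble feature-selection frameworks with pooled Shapley-value
    attribution: clique-forming feature selection (CFFS) over low-correlation
    feature graphs and adaptive hybrid feature selection (AHFS) driven by
    information-theoretic candidate measures. Includes a seeded synthetic
    actigraphy cohort generator with injectable group effects for end-to-end
    testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    nnet,
    purrr,
    randomForest,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
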