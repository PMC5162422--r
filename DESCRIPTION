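Package: evoonmr
Title: Chemometric Analysis of Single-Tree Olive Oil 1H NMR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for 1H NMR metabolomic profiling of
    extra-virgin olive oil cohorts sampled from individual trees across
    cultivars and harvest years. Provides spectral bucketing with exclusion
    regions, total-sum normalization and Pareto scaling, Hotelling T2
    outlier screening, PCA, multi-class PLS-DA and binary OPLS-DA with
    7-fold cross-validated Q2 and response permutation testing, S-line
    loadings, cluster-separation metrics (the J2 determinant-ratio
    criterion and group Mahalanobis distances in PCA score space), and a
    paired plant-level analysis of between-harvest Mahalanobis distance
    distributions. A synthetic spectrum generator emulating
    cultivar, harvest-year and per-plant variance structure makes every
    stage testable without acquired spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    MASS,
    withr
Config/testthat/edition: 3
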