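Package: tangentfc
Title: Tangent-Space Analysis of Functional Connectome Reconfiguration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies brain functional reconfiguration between fMRI
    conditions on the manifold of symmetric positive-definite (SPD)
    functional connectomes. Parcellated BOLD time series are segmented,
    correlated into functional connectomes, regularized, and projected onto
    the tangent space at a Riemannian (Karcher) mean reference; tangent
    connectomes are compared by correlation distance to build
    identifiability and meta-identifiability matrices, fingerprinting
    identification rates, and per-participant reconfiguration vectors,
    which feed additive multilinear regression models of risk covariates,
    leave-one-out stability analyses, and regularization sweeps. A seeded
    synthetic cohort generator emulates the fingerprint, task, scan and
    covariate-effect structure of a rest/task/rest study design so the full
    pipeline is testable without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
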