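Package: dbmcov
Title: Structural Covariance and Trajectory Analysis for Deformation-Based
    Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-brain analysis of longitudinal deformation-based
    morphometry (DBM) in mouse models of synucleinopathy. Converts
    per-scan log-Jacobian determinant volumes into analysis-ready
    voxel-by-subject matrices, decomposes them with orthogonal projective
    non-negative matrix factorization (OPNMF) using split-half stability
    and reconstruction-error-gradient model selection, quantifies overlap
    of sex-specific spatial patterns with the Dice similarity coefficient,
    maps voxel-wise group-by-sex-by-time trajectories with fast
    random-intercept mixed models under FDR control, and performs
    censoring-aware survival and motor-behavior inference (Cox
    proportional hazards with task latency cutoffs, longitudinal mixed
    models, Bonferroni correction). Includes a synthetic cohort generator
    with planted spatial atrophy components, hazard-linked attrition and
    task latency ceilings, so every stage can be validated against known
    ground truth.
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
    jsonlite,
    purrr,
    RNifti,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lme4,
    lmerTest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
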