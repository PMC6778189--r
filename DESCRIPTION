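Package: deltarad
Title: Delta-Radiomics Feature Screening and Treatment-Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Longitudinal (delta-) radiomics analysis of 3D image regions of
    interest: gray-level co-occurrence, run-length, neighbourhood gray-tone
    difference, intensity-histogram and shape features; the NESTD
    (normalized entropy-to-standard-deviation difference) boundary feature;
    delta-radiomic features relative to a baseline fraction with weekly
    aggregation; a statistical screening cascade (Spearman redundancy
    filter, coefficient-of-variation robustness graded with a modified
    signed likelihood-ratio test, scanner-effect checks, trend regression,
    and a crossed random-intercept mixed-model likelihood-ratio test); batch
    self-organizing-map correlation checks; and a Bayesian-regularization
    neural-network classifier with a Mahalanobis-distance Gaussian
    discriminant, leave-one-patient-out cross-validation and bootstrap
    ensembling. Includes synthetic longitudinal cohort generators (image
    level and feature level) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    pROC
Config/testthat/edition: 3
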