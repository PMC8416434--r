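Package: qeegclass
Title: Quantitative EEG Spectral Features and Cross-Validated Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building quantitative EEG (QEEG) classifiers from
    resting-state recordings on the 19-channel 10-20 montage. Computes
    sliding-window FFT cross-spectra, band-wise absolute power and
    magnitude-squared coherence, assembles feature matrices over a
    combinatorial grid of spectral parameters, bands and covariates, and
    evaluates elastic-net, support-vector and random-forest classifiers
    under stratified 10-fold cross-validation with feature-survival
    extraction and permutation significance testing. Includes a synthetic
    resting-state EEG cohort generator with controllable band-power and
    coupling group effects for end-to-end validation without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    purrr,
    randomForest,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
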