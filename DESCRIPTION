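Package: ftirtax
Title: Chemotaxonomic Classification of Fossil FTIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A chemometric pipeline for discriminating fossil taxa preserved
    in chert from their infrared (FTIR) molecular fingerprints. Provides a
    spectral data model with CSV and minimal JCAMP-DX input, composable
    history-tracked preprocessing (truncation, ALS and rubberband baseline
    correction, Gaussian smoothing, silica-peak and vector normalization,
    Savitzky-Golay derivatives), absorption-band feature extraction with an
    aliphatic CH3/CH2 chain-length estimate, data exploration by PCA with
    bootstrap loading stability and Hotelling T2 / Q-residual outlier
    screening, native canonical correspondence analysis, supervised binary
    discrimination (stratified splitting, SMOTE class balancing, LDA and
    RBF-SVM with leave-one-out grid search, five performance metrics),
    one-class modelling by data-driven SIMCA with chi-square acceptance
    regions, and a seeded synthetic-spectrum generator that emulates the
    study design of a multi-taxon chert assemblage so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    e1071,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
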