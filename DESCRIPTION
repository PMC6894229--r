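Package: perimetab
Title: Perioperative Carbohydrate NMR Metabolomics Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of 1H-NMR serum and tumor-tissue
    metabolomics in a perioperative carbohydrate-loading versus fasting
    design. Provides a synthetic cohort generator (Lorentzian spectrum
    forward model, clinical covariates calibrated to target correlations,
    exponential proportional-hazards outcomes), frequency-domain spectral
    preprocessing (chemical-shift referencing, region selection, asymmetric
    least squares baseline correction, total-area normalization, peak-window
    integration), univariate group statistics with signed fold changes and
    Benjamini-Hochberg control, NIPALS partial least squares (PLS and
    PLS-DA) with leave-one-out cross-validation, permutation testing and
    VIP variable ranking, and ROC-threshold-driven survival analysis
    (Kaplan-Meier, log-rank, Cox regression with forward Wald selection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
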