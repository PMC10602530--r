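Package: scrsdx
Title: Single-Cell Raman Spectral Diagnostics for Fatigue Disease Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for diagnosing fatigue diseases (ME/CFS and
    multiple sclerosis) from single-cell Raman spectra of peripheral blood
    mononuclear cells. Provides a synthetic cohort generator with Lorentzian
    peak models, fluorescence baselines and cosmic-ray spikes; chemometric
    preprocessing (despiking, polyline baseline correction, vector
    normalization, SNR quality control, per-cell averaging); Raman band
    integration for relative metabolite quantification with Welch tests;
    shrinkage linear discriminant analysis for visualization and feature
    selection; a two-layer stacked ensemble classifier (eight base learners
    with out-of-fold probability stacking through a gradient boosting
    meta-learner) with cell-to-subject aggregation and exact binomial
    confidence intervals; and ordinal symptom-burden statistics (fold-change
    screening, Fisher exact tests, Benjamini-Hochberg adjustment).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    nnet,
    rpart,
    randomForest,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
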