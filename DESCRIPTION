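Package: thermoHb
Title: Thermal-Stimulation fNIRS Oxyhemoglobin Biomarkers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of functional near-infrared spectroscopy
    (fNIRS) recordings acquired during cold-pressor thermal stimulation, aimed
    at candidate hemodynamic biomarkers of fibromyalgia. Provides a seeded
    synthetic cohort generator (dual-wavelength optical intensities, paradigm
    timelines, clinical covariates), coefficient-of-variation channel quality
    control, modified Beer-Lambert conversion to oxy/deoxyhemoglobin, zero-phase
    band-pass filtering, region-of-interest feature extraction (peak latency,
    baseline-to-peak and post-stimulus oxyhemoglobin changes), generalized
    estimating equations with exchangeable working correlation and sandwich
    covariance, Spearman and multivariate severity models, a priori sample-size
    computation, and ROC screening with Youden-index cutoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    pROC,
    knitr
biocViews: Software, TimeCourse, Preprocessing, QualityControl, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
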