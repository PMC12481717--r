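Package: tactileERP
Title: Somatosensory Evoked-Potential Analysis with Dynamic Coefficient-of-Variation and Reliability Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multi-level tactile (electro-tactile) EEG experiments
    in young children: synthetic two-group evoked-EEG cohort generation with ground-truth
    component templates, EDF input/output, preprocessing (zero-phase Butterworth band-pass
    filtering, epoching, baseline correction, bad-channel interpolation, peak-to-peak
    artifact rejection), peak-window ERP component quantification (P100, N140, P200, N200,
    P300), two-factor ANCOVA with an age covariate and Type III sums of squares, LSD
    post-hoc comparisons, partial eta-squared effect sizes, noncentral-F power analysis,
    per-electrode topographic statistics, a sliding-window across-level coefficient of
    variation statistic, two-way random-effects absolute-agreement intraclass correlation
    (ICC(2,1)) reliability, and stratified k-fold group classification with SVM, LDA and
    a three-layer neural network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    signal,
    car,
    emmeans,
    e1071,
    MASS,
    nnet,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
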