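Package: gcdoa
Title: Granger-Causality Features for Awake Versus Anesthetized EEG State Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pairwise time-domain Granger causality (GC) analysis of multichannel
    EEG for discriminating the awake from the anesthetized brain state. Implements
    region averaging over the 10/20 montage, sliding-window segmentation with
    stationarity (KPSS), Durbin-Watson and model-consistency admission gates,
    univariate/bivariate autoregressive fits with BIC order selection, directed
    and instantaneous GC for all region pairs, phase-randomized surrogate
    significance thresholds, a source-shift (SOBI) surrogate control for volume
    conduction, and a bootstrap classification study (LDA, linear and RBF SVM)
    reporting specificity, sensitivity and average accuracy with ANOVA
    comparisons. A state-switching vector-autoregressive generator produces
    synthetic recordings with fronto-to-posterior coupling that switches on
    under anesthesia, so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
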