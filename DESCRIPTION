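Package: gaitsev
Title: Severity Grading of Parkinsonian Gait from Plantar Force Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for grading Parkinson's disease severity (Hoehn-Yahr
    classes Healthy, 2, 2.5 and 3) from 18-channel vertical ground reaction
    force (VGRF) recordings sampled at 100 Hz. Provides a reader/writer for
    the plain-text walk-file dialect used by public plantar-pressure gait
    archives, a labelled synthetic gait simulator, seven composable
    time-series augmentation operators (jittering, scaling, rotation,
    magnitude warping, permutation, time warping, random sampling),
    a linear-prediction-residual transform with decimation, fixed-window
    segmentation with subject-independent cross-validation and majority
    voting, two small sequence classifiers (a per-channel 1D convolutional
    network and a time-spatial attention encoder) trained with Nadam and
    early stopping, and an evaluation harness covering augmentation
    comparison, significance testing and symmetric sensor-pair ablation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
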