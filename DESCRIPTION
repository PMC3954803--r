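Package: nirsvigilance
Title: Attention-State Classification from Functional Near-Infrared
    Spectroscopy Signals
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for sustained-attention
    (psychomotor vigilance) experiments monitored with multichannel
    continuous-wave functional near-infrared spectroscopy (fNIRS).
    Generates synthetic multi-subject cohorts of oxy- and
    deoxy-hemoglobin time series with ground truth, preprocesses them
    (modified Beer-Lambert law conversion with age-specific differential
    pathlength factor, zero-phase Butterworth low-pass filtering,
    movement-artifact reduction by moving standard deviation detection
    and spline correction, z-normalization), builds one-second epoch
    feature tables over region-by-chromophore design spaces, classifies
    full-attention versus attention-decrement states with a linear
    soft-margin support vector machine under leave-one-subject-out
    cross-validation, and reproduces the reaction-time block analysis
    (paired t-test and Cohen's d of change).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    data.table,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
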