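Package: maldimix
Title: Multivariate Calibration of Two-Component Cell Mixtures from
    Intact-Cell MALDI-TOF Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the level of cross-contamination in two-component
    cell mixtures (for example a feeder-cell contaminant in a stem-cell
    culture) from intact-cell MALDI-TOF mass-spectral fingerprints.
    Implements a five-step preprocessing chain (resampling to a uniform
    m/z grid, alignment, baseline subtraction, Savitzky-Golay smoothing,
    sum-to-one normalization) with an intensity-threshold peak filter,
    informative-peak selection by normalized standard deviations, Lasso
    and sparse partial least squares, PCA diagnostics, and two calibrators
    benchmarked against each other: NIPALS PLS1 and a single-hidden-layer
    back-propagation neural network, both evaluated by leave-one-out
    cross-validation with root-mean-square error, regression slope and
    determination coefficient.  A synthetic spectrum generator emulating
    shared and marker peaks, nonlinear ionization response, suppression,
    jitter, baseline and noise makes the full pipeline testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    signal,
    glmnet,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mzR,
    mixOmics,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
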