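Package: gsbias
Title: Global-Signal-Induced Bias in fMRI Rigid-Body Motion Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and characterizes the bias that resting-state global
    brain activity induces in rigid-body fMRI motion estimates, using the
    difference between motion parameters estimated from two echoes of
    multi-echo fMRI data. Provides a synthetic multi-echo phantom generator
    with known ground-truth motion and a global BOLD fluctuation with
    controllable spatial asymmetry, an intensity least-squares rigid-body
    registrar with uniform weights, percent-change and global-signal
    preprocessing, permutation-null significance testing of the correlation
    between the motion-estimate difference and the global signal, a
    spatial-map decomposition of that correlation into beta-coefficient and
    derivative-image contributions, and an analysis of the downstream effect
    of biased motion regressors on ROI-ROI functional connectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
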