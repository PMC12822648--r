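Package: mvpainfo
Title: Cross-Decoding MVPA of Object Shape with Classifier Information and
    Synthetic BOLD Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A multivariate pattern analysis (MVPA) pipeline for fMRI
    cross-decoding studies of proximal object shape. Provides a synthetic
    BOLD generator emulating two event-related experiment designs with
    known ground truth, general linear model estimation with canonical and
    finite impulse response bases, localizer-ranked nested sub-ROI voxel
    selection, linear support-vector decoding scored with a distance-to-bound
    "classifier information" statistic, group inference by one-dimensional
    threshold-free cluster enhancement (TFCE) with sign-flip permutation,
    univariate region and whole-brain cluster contrasts, an
    information-activation coupling analysis, and Monte-Carlo calibration
    harnesses for type-I error and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    MASS,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
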