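Package: collfilt
Title: Collateral Filtering and Automated Restoration of Brain MR Images
Version: 0.1.0
Authors@R: person("CBEL", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Edge-preserving restoration of brain magnetic resonance images
    with the collateral filter, a bilateral-type filter whose radiometric and
    median-filtered range kernels are balanced per pixel by a windowed entropy
    of the image/median agreement probability. Provides a reference per-pixel
    backend and an algebraically equivalent tiled backend with precomputed
    spatial-weight, entropy and blend buffers; a 95-entry texture feature bank
    (statistical, gray-level co-occurrence, gray-level run-length, Tamura,
    and seven noise-level estimators); paired t-test feature ranking and
    sequential forward floating selection; brute-force peak signal-to-noise
    ratio parameter search and a two-stage feed-forward neural network
    (noise-class classifier routing to per-class parameter regressors) trained
    by Levenberg-Marquardt; image quality metrics; and a seeded generator of
    brain-like phantoms with tissue classes, slice-thickness smoothing,
    multiplicative bias fields and Rician noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
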