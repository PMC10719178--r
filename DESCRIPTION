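Package: ybremdose
Title: Quantitative Yttrium-90 Bremsstrahlung SPECT Reconstruction and Voxel Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for quantitative yttrium-90 (90Y)
    bremsstrahlung SPECT and voxel-level dosimetry in radioembolization.
    Provides synthetic virtual-patient and torso phantom generation, a
    rotation-based parallel-hole SPECT projector with attenuation and
    depth-dependent collimator-detector response, a simplified photon
    Monte Carlo producing ground-truth scatter and primary projections, a
    projection-space convolutional scatter-estimation network, ordered-subsets
    expectation-maximization (OS-EM) reconstruction with scatter correction,
    90Y beta-particle dose-voxel-kernel generation and FFT convolution
    dosimetry with density scaling, a condensed-history electron Monte Carlo
    for heterogeneous-medium dose-rate maps, a residual-learning dose-map
    network, and the evaluation metrics used in radioembolization dosimetry
    (NMAE, NRMSE, dose-rate volume histograms, lesion-to-background ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
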