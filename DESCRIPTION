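Package: vcsd
Title: Volumetric Current Source Density Reconstruction from 3D
    Microelectrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs volumetric current source density (CSD) in
    cortical tissue from extracellular potentials recorded with
    three-dimensional microelectrode arrays. Implements a
    Laplacian-regularized (LORETA-type) linear inverse with generalized
    cross-validation for the regularization weight, forward lead fields
    for an infinite homogeneous medium and for a multi-shell anisotropic
    spherical volume conductor computed by Legendre-series expansion, an
    approximate inverse-CSD (iCSD3D) baseline, phantom simulation and
    validation experiments (volume-conductor mismatch, noise by electrode
    pitch sweeps), functional-barrel localization against anatomical
    masks, and a preprocessing front-end for multichannel recordings
    (band separation, evoked-response averaging, threshold spike
    detection, spike-triggered averaging).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
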