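Package: histotomo
Title: Quantitative Cell-Level Phenotyping for Whole-Animal X-Ray Histotomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative computational phenotyping of whole-animal
    synchrotron micro-CT ("histotomography") volumes of small vertebrates such
    as larval zebrafish. Provides a synthetic phantom generator with known
    ground truth, a contrast-to-noise model for X-ray beam-energy selection
    over tabulated mass-attenuation coefficients (including absorption edges),
    voxel-feature random-forest nucleus detection with orthogonal-plane
    probability fusion and size filtering, 3D shape morphometry (volume,
    moment-based elongation, line-profile periodicity and modulation depth),
    landmark-based affine and thin-plate-spline registration with label-map
    transfer and spherical-neighborhood cell-density maps, and cross-specimen
    region statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ranger,
    jsonlite,
    stats,
    utils,
    grDevices,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
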