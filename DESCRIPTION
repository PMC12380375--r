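Package: chemholo
Title: Forward and Inverse Optical Models for Phase-Sensitive Mid-Infrared Chemical Holography
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for chemical holography:
    quantitative phase imaging with a coherent mid-infrared source. Provides a
    coupled-wave forward solver for layered samples, a scalar Mie model for
    spherical scatterers with order-0 discrete Hankel transforms and numerical-
    aperture band-limiting, synthesis and least-squares reconstruction of
    phase-stepped interferograms, a grid-search inversion recovering thickness
    and complex refractive index of a layer from its optical path length, and a
    small dense-network pipeline that solves the ill-conditioned inverse Mie
    problem from one-dimensional complex or intensity field representations,
    including Gaussian-noise, aperture-bandpass and two-sphere robustness
    sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
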