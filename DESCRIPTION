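Package: phototherm
Title: Treatment Planning for Gold-Nanoparticle Photothermal Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation pipeline for planning pulsed-laser photothermal
    therapy of skin tumors loaded with gold nanorods. Builds a voxelized
    multilayer skin phantom, runs Monte Carlo photon transport
    (Henyey-Greenstein scattering, weighted absorption deposition) to map
    laser energy deposition, integrates the heat-diffusion equation with an
    explicit finite-difference scheme under on/off laser duty cycles, and
    scores treatment quality with apoptosis-band retention and thermal-hazard
    metrics. A parameter sweep over laser power, nanoparticle volume fraction
    and cooling-time ratio locates optimal treatment conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
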