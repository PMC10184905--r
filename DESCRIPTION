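Package: consortsim
Title: Individual-Based Simulation of a Sucrose-Mediated Phototroph-Heterotroph Consortium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Individual-based model of a synthetic microbial consortium in
    which a sucrose-secreting cyanobacterium cross-feeds a heterotrophic
    partner. Cells are spherical agents with Monod growth kinetics and an
    inducer-dependent sucrose secretion flux; nutrients are continuous
    reaction-diffusion fields solved on a Cartesian grid with per-nutrient
    boundary conditions. Includes colony-level spatial statistics
    (nearest-neighbour and inter-colony distances, Voronoi tessellation
    areas), a neural-network regression that predicts colony fitness from
    initial spatial structure with permutation feature importance, and
    two-step calibration of the growth and secretion terms by parameter
    recovery on synthetic time series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
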