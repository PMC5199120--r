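Package: carousel
Title: Carousel Model of GPCR, G-Protein and RGS Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action kinetic modelling of heterotrimeric G-protein
    activation by a G-protein-coupled receptor (GPCR) whose GTPase-accelerating
    regulator (RGS) is physically localized to the receptor. Implements the
    "carousel" reaction network that composes the ternary complex model with
    the three-state G-protein cycle, a steady-state solver stable across
    eight-decade parameter variation, steady-state dose-response simulation
    with amplitude, EC50 and dose-response-alignment (DoRA) summaries,
    log-uniform Latin hypercube sampling of the kinetic parameter space, and a
    global robustness scan that classifies parameter points by the
    insensitivity of their dose-response curves to receptor abundance and
    mines the pairwise parameter restrictions that enable fractional-occupancy
    measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
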