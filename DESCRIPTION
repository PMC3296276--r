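Package: adcycle
Title: Stochastic Kinetic Modelling of the GSK3beta/p53/ROS Cycle in
    Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact stochastic simulation (Gillespie direct method) of a
    mass-action reaction network linking amyloid-beta production,
    clearance and aggregation to tau phosphorylation and tangle
    formation through a positive-feedback cycle involving reactive
    oxygen species, DNA damage, p53 and GSK3beta.  Provides the default
    Alzheimer's-disease network, timed intervention events (staggered
    amyloid-beta clearance boosts, ROS-production and GSK3beta/p53
    binding blockades), ensemble simulation with reproducible seeding,
    ensemble summaries, a threshold-based neuronal-viability analysis,
    and plain-text/SBML serialisation of models and results.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
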