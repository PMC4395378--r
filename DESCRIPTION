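Package: axevolve
Title: Regulatory Evolution of Voltage-Gated Channel Expression in the
    Squid Giant Axon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Couples a modified Hodgkin-Huxley model of the propagating
    action potential in the squid giant axon (nonlinear gating capacitance,
    Clay potassium-channel deactivation kinetics, staggered backward-Euler
    cable solver) with a diploid K-allele Wright-Fisher model of
    cis-regulatory evolution.  The cable model defines a physiological
    fitness landscape over sodium and potassium conductance space --
    conduction failure thresholds, conduction velocity, sodium flux,
    action potential duration and Type 2/Type 3 excitability -- and the
    population model evolves channel expression levels under biased
    stepwise mutation, fitness-cliff selection and binomial phenotypic
    noise, locating the selection-mutation balance conductances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
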