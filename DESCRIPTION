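Package: hpnfate
Title: Hybrid Petri Net Simulation and Simulative Model Checking of p53-Driven
    Cell Fate Decision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construct, simulate and verify hybrid Petri nets (HPN) that couple
    a stochastic subnet (exponentially timed transitions on integer markings)
    with a continuous subnet (marking-dependent flows interpreted as ordinary
    differential equations). Ships a cell-fate decision model in which ionizing
    radiation induces Poisson-distributed DNA double-strand breaks, the nuclear
    p53 signalling network is simulated stochastically, the cytoplasmic
    apoptosis pathway is integrated deterministically, and nucleus-to-cytoplasm
    mRNA transport bridges the two regimes. A probabilistic linear temporal
    logic (PLTL) layer evaluates path formulas on finite simulation traces and
    estimates, over seeded trace ensembles, the probabilities that total p53
    shows zero, one, or multiple pulses per radiation dose.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
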