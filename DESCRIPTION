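Package: ontoradiate
Title: Adaptive Radiation in Size-Structured Consumer-Resource Systems with
    Ontogenetic Diet Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of adaptive radiation in consumers whose
    diet shifts during growth. Small individuals feed on a shared resource and,
    above a threshold body mass, gain access to a set of species-specific
    resources on which they can specialize through a heritable niche trait.
    Three engines share one bioenergetic closure: a deterministic equilibrium
    solver for the physiologically structured population model (with parameter
    continuation exposing ecological bistability), an adaptive-dynamics engine
    (invasion fitness from the lifetime reproductive number, singular-strategy
    classification, trait-substitution simulation of evolutionary branching),
    and a stochastic individual-based model with diploid multi-locus genetics
    and evolvable assortative mating, used to study speciation with gene flow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
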