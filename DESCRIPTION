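Package: ddevo
Title: Eco-Evolutionary Loss of Metamorphosis and Correlated Evolution of
    Direct Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study when a metamorphosing consumer population evolves
    direct development. Implements a size-structured consumer-resource model
    with irreversible and reversible body mass, life-history integration and
    resident equilibria (R0 = 1), adaptive-dynamics machinery (invasion
    fitness, selection gradients, singular strategies and their
    classification, continuation in supply rates, canonical-equation
    trajectories), a stochastic individual-based eco-evolutionary simulator,
    and a Bayesian test of correlated evolution for two binary traits on a
    phylogeny (independent, dependent and constrained Pagel-type Markov
    models, pruning likelihoods, MCMC, stepping-stone marginal likelihoods
    and Bayes factors), together with generators for synthetic trees, traits
    and parameter presets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Matrix,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
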