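Package: aquaevol
Title: Irreversible Markov Models and State-Dependent Body-Mass Trends for
    Aquatic Adaptation in Mammals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phylogenetic comparative tools for studying ordered, partially
    irreversible transitions among discrete levels of aquatic adaptation and
    their phenotypic correlates. Implements constrained four-state Markov
    models (equal-rates, symmetric, ordered, all-rates-different, and three
    irreversibility variants), Felsenstein pruning likelihoods with the
    FitzJohn-Maddison root treatment, AICc model ranking and Akaike-weight
    model averaging of rate matrices, stochastic character mapping by
    uniformization with transition-count and clade-rate summaries, a
    stochastic-mapping D-test of correlated evolution between two discrete
    traits with posterior-predictive significance, and a hierarchical
    Bayesian Brownian-motion model of log body mass with clade-specific
    rates and aquatic-state-specific trend parameters sampled by MCMC.
    A built-in simulator generates birth-death trees, discrete histories and
    continuous traits with known truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
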