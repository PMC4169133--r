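Package: heterochron
Title: Bayesian Ancestral State Reconstruction and Heterochrony Polarization on Chronograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for polarizing heterochronic shifts (acceleration,
    deceleration, stasis; neoteny versus progenesis) in developmental
    timing on time-calibrated phylogenies. Implements ordered multistate
    Markov models with structural-zero transition constraints, Felsenstein
    pruning likelihoods with missing data, maximum-likelihood model fits
    with AIC comparison, Metropolis-Hastings MCMC over posterior tree
    samples with node fossilization and harmonic-mean marginal
    likelihoods (Log Bayes factor tables), Brownian-motion continuous
    ancestral reconstruction with highest-posterior-density intervals,
    tip classification against ancestral credibility intervals, a
    progenesis-versus-neoteny test across a life-history transition, and
    seeded generators for synthetic chronograms and trait tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    phangorn,
    phytools,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
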