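Package: epiworth
Title: Pairwise Epistasis, Model Adequacy, and the Worth of a Site in
    Phylogenetic Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and diagnosis tools for studying the effect of
    unmodeled pairwise epistasis on Bayesian phylogenetic inference. Implements
    the 16-state RNA doublet substitution model with Watson-Crick double
    substitutions, a seeded simulator for alignments mixing independent and
    epistatically paired sites along a tree, Felsenstein pruning likelihoods
    for both the 4-state GTR+G and the doublet model, a Metropolis-Hastings
    sampler for deliberately misspecified site-independent GTR+G inference with
    ASDSF/PSRF convergence filtering, posterior predictive adequacy checks
    based on the multinomial (G93) statistic and on pairwise mutual information
    summaries (MImax, MIkurt), Robinson-Foulds accuracy and majority-rule
    consensus precision summaries, and a monotone I-spline regression that
    estimates the relative worth r(d) of an epistatically paired site in units
    of independent sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    pracma,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
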