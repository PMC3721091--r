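Package: IsingZ
Title: Missing-Mass Approximation of Stimulus-Driven Ising Partition Functions
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for normalizing stimulus-driven pairwise maximum-entropy
    (Ising) models of binned population spike trains. The stimulus-dependent
    partition function Z(s) is approximated by summing the unnormalized
    weights of spike patterns observed in the training data exactly and
    correcting for the remainder through the stimulus-modulated missing mass,
    estimated either by the Good-Turing singleton count or by a normalized
    chain of conditional logistic regressions ordered by firing rate.
    Includes exact enumeration for small populations, Monte Carlo importance
    sampling, naive/TAP mean-field, Bethe (loopy belief propagation) and
    low-firing-rate baselines, pseudo-likelihood model fitting, a Gibbs
    simulator of trial-structured stimulus-driven populations with B-spline
    or Zernike drive, and ratio-distribution evaluation utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, splines, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
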