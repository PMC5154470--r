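Package: vbhmm
Title: Variational Bayes Hidden Markov Models for Dynamic Functional
    Connectivity States
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits hidden Markov models with multivariate Gaussian emissions
    by variational Bayes, using Dirichlet priors on the initial and
    transition distributions and Normal-Wishart priors on the state means
    and precisions. Intended for discovering time-varying connectivity
    states in multi-subject, multi-region time series (e.g. resting-state
    fMRI region-of-interest series): redundant states are pruned
    automatically by the sparse priors, state sequences are recovered by
    Viterbi decoding, and per-state dynamics (occupancy rates, mean
    lifetimes, transition probabilities) are summarized at the subject and
    group level. Per-state partial-correlation networks are extracted from
    the regularized covariance estimates, node communities are found with a
    signed Louvain algorithm, and states sharing a community structure are
    merged into dynamic functional networks. Includes simulators for three
    validation designs (block-design correlation switching, HMM-generated
    covariance states, and split-half correlation states).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
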