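Package: priorheur
Title: Fast-and-Frugal Heuristics as Extreme-Prior Bayesian Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models binary paired-comparison decisions on a continuum between
    fast-and-frugal heuristics and linear regression, indexed by the strength
    of a Bayesian prior. Implements the half-ridge model (a Gaussian prior on
    cue weights truncated to the orthant fixed by known cue directions, whose
    strong-prior limit is the directed tallying heuristic and whose weak-prior
    limit is sign-constrained regression) and the covariance orthogonalizing
    regularization (COR) model (a multiplexed-outcome regression whose penalty
    on cross-weights suppresses sensitivity to cue covariance, recovering
    ordinary regression, take-the-best, and tallying in its limits). Also
    provides the tallying and take-the-best heuristics with cue validities, a
    synthetic generator of correlated binary-cue environments, and a seeded
    cross-validation harness for prior-strength sweeps and model comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
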