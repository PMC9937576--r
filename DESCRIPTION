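Package: coopevo
Title: Evolutionary Dynamics of Universal and Parochial Cooperation in
    Group-Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the evolution of cooperation in populations divided into
    groups, where agents can fund an excludable club good for their own group,
    a population-wide public good, or free-ride, and where cooperation is
    enforced through a dyadic reciprocal helping stage whose partner choice is
    governed by the fluidity of group boundaries. Provides an exact solver for
    the stationary distribution of the frequency-dependent Moran process over
    the full population state space, closed-form invasion and maintenance
    thresholds, and a fast agent-based simulator (with a compiled core) for
    large and fragmented populations and for extended strategy spaces with
    nondiscriminating helpers and second-order free-riders. Includes parameter
    sweeps, config and result serialization, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
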