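Package: quorumsdt
Title: Quorum Decision Rules for Collective Binary Choice via Signal
    Detection Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing collective binary decision-making by groups
    of conditionally independent voters. Individual decision-makers facing a
    two-state world with Gaussian cue distributions are optimised by signal
    detection theory (likelihood-ratio criterion, closed-form threshold, ROC
    curves); group accuracy under an arbitrary quorum rule is computed
    exactly from binomial tails, by Monte Carlo simulation, or in the
    large-group limit. The package classifies decision scenarios into the
    predictive errors that Condorcet-style majority reasoning makes when the
    two error types (false positives and false negatives) have unequal
    rates, maps those error regions over prior probability and error-cost
    ratio, and recommends sub- or super-majority quorums from the optimal
    quorum interval.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
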