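Package: rsgr
Title: Reversed Sample Generation by Replacement for Fake-Good Ordinal Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Probabilistic reconstruction of hypothetical honest responses
    from suspected fake-good ordinal questionnaire data. Implements the
    discrete generalized beta replacement family with uninformative, slight
    and extreme faking scenarios, entrywise reverse (reconstruction) and
    forward (corruption) perturbation of Likert-type response matrices, a
    calibrated latent one-factor generator for correlated ordinal data with
    binomial-shaped marginals, maximum-likelihood one-factor confirmatory
    factor analysis with NFI/CFI/NNFI/RMSEA fit indices and improper-solution
    flagging, and a Monte-Carlo scenario grid summarised by the average
    relative bias (ARB) statistic against control statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
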