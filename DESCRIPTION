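Package: veribayes
Title: Bayesian Estimation of Diagnostic Test Accuracy Under
    Verification Bias
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Bayesian estimation of the individual and combined accuracy
    of two diagnostic tests when some subjects are not verified by the
    gold standard (verification bias).  Under the missing-at-random
    assumption the joint test-outcome probabilities have a Dirichlet
    posterior and the per-cell disease probabilities have beta
    posteriors, so all accuracy measures are obtained by direct Monte
    Carlo sampling: true and false positive fractions of each test and
    of the believe-the-positive and believe-the-negative combined
    rules; detection and false referral probabilities with their BP:BN
    ratios under extreme verification bias; ROC areas of paired ordinal
    tests; inverse-probability-weighting imputation of a biased table;
    and the ROC area of a Bayesian logistic risk score as the combined
    accuracy of two ordinal tests.  Includes a generator of synthetic
    verification-bias data for parameter-recovery studies and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
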