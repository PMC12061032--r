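Package: kappaML
Title: Maximum-Likelihood Interrater Reliability Under an Occasional-Guessing Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chance-corrected agreement coefficients for two raters classifying
    cases into categories. Implements the maximum-likelihood kappa under the
    occasional-guessing model of chance agreement, in which a fraction r of
    cases are hard (raters guess uniformly) and the rest are easy (raters
    always agree on the true label). Under this model the maximum-likelihood
    estimate of the chance-agreement probability is the observed disagreement
    rate, and the resulting guessing-fraction estimate is unbiased. Cohen's
    kappa and Gwet's AC1 are provided for comparison, together with the
    analytic variance of the guessing-fraction estimate, normal, Lipschitz,
    monotone-map and percentile-bootstrap confidence intervals, a generative
    simulator for the occasional-guessing model, and a Monte-Carlo sweep that
    quantifies the finite-sample bias of each coefficient across the full
    range of true reliability.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
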