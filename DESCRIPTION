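Package: socbayes
Title: Bayesian Integration of Prior Value Beliefs with Social Review Information
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a descriptive Bayesian model of how people revise product value
    judgments after seeing aggregate review information (mean stars, number of
    reviewers). Each participant's first rating is modelled as a draw from a
    Gaussian prior whose variance depends on stated confidence, the reviews act
    as a Gaussian likelihood whose precision depends on reviewer count, and the
    second rating is a draw from the conjugate posterior. Provides per-participant
    maximum-likelihood fitting with the product-level prior means profiled out in
    closed form, trial-wise Kullback-Leibler divergence as the magnitude of belief
    update, a per-participant resistance index (the Bayesian weight of the prior),
    the accompanying hierarchical regression battery for the behavioral
    signatures of reliability-weighted integration, and a seeded synthetic-cohort
    generator with the statistical structure of a two-phase rating study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
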