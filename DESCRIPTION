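Package: linkshrink
Title: Linked Shrinkage Regression for Two-Way Interactions with
    Interventional Shapley Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian linear regression with all two-way interactions under a
    linked local shrinkage prior: each interaction coefficient borrows its
    prior scale from the half-Cauchy local scales of its two parent main
    effects, times a global interaction shrinkage factor. Fits the model and
    its variants by a blocked Gibbs sampler with exact conditional updates,
    and provides exact closed-form interventional Shapley values with
    posterior credible intervals, personalized unit-change effects,
    range-of-significance summaries, credible-interval variable selection,
    estimator evaluation (per-coefficient rMSE, linear-predictor MSE,
    sensitivity at fixed empirical FDR), and seeded simulation designs with
    known truth for recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    mvtnorm,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
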