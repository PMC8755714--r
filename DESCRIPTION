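Package: epochdiv
Title: Episodic Birth-Death Models of Environmentally Linked Diversification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian estimation of time-varying speciation and extinction
    rates from time-calibrated phylogenies under the episodic birth-death
    process.  Implements an empirical (clade-informed) taxon-sampling model
    that integrates over the unknown speciation times of missing species,
    uncorrelated lognormal and Markov-random-field (Gaussian and horseshoe)
    priors on epoch-wise rates, and four environmentally dependent
    diversification models that link rate changes to a paleoenvironmental
    time series (for example atmospheric CO2) through a correlation factor.
    Includes an adaptive MCMC engine, stepping-stone marginal-likelihood
    estimation, posterior-odds Bayes factors for the sign of the
    environmental correlation, and a forward simulator of episodic and
    environment-linked birth-death trees for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
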