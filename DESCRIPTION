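Package: dtmarkov
Title: Discrete-Time Markov Models with Flexible Covariate Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits discrete-time Markov models of competing transitions in
    which per-individual transition probabilities are predicted from
    covariates by constant, linear, or neural-network mappings through a
    multinomial-logistic link. The likelihood supports exactly observed,
    right-censored, and interval-censored transition times; training uses
    minibatch ADAM on the negative log-likelihood. Includes a synthetic-data
    generator for star-topology competing-risk data with proportional
    probability noise and Poisson interval censoring, and an evaluation
    suite covering validation likelihood, Brier scores via
    Chapman-Kolmogorov state occupation, per-transition mean squared error,
    and paired model comparisons across replicate datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
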