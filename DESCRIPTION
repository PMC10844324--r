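Package: bcibind
Title: Bayesian Causal Inference Models of Intentional Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generative observer models of action and outcome timing reports
    in the Libet-clock paradigm, covering the full model space used to study
    intentional binding: Bayesian causal-inference observers (joint-posterior,
    model-selection, model-averaging and probability-matching strategies,
    each with a unity or coupling temporal prior), mandatory integration,
    fixed-criterion averaging, false-report and null models. Provides a
    synthetic-experiment simulator, Monte-Carlo maximum-likelihood fitting
    with kernel-density trial likelihoods, AIC model comparison, parameter-
    and model-recovery pipelines, and descriptive temporal-binding indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
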