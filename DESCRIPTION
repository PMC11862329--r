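Package: bufferscape
Title: Structured Demographic Buffering in Stochastic Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for exploring how environmental autocorrelation
    and variance shape demographic buffering in size-structured populations.
    Builds environmentally explicit, parameter-stochastic integral projection
    models (IPMs), drives them with AR(1) environmental timeseries rescaled to
    exact target moments, estimates stochastic growth rates, computes numerical
    stochastic elasticities of variance for whole kernels and for the
    progression and fertility subkernels, derives population-structure
    diagnostics (average size distribution, buffering deviance, mean buffered
    size), and partitions landscape variance among environmental components via
    polynomial regression with AIC model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
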