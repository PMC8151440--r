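Package: ivivc
Title: One- and Two-Step Level-A In Vitro-In Vivo Correlation Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and validating level-A in vitro-in vivo
    correlations (IVIVC) for oral drug products: two-compartment disposition
    algebra and fitting, non-compartmental analysis with cross-study
    normalization, three-parameter Weibull dissolution modelling and the f2
    similarity factor, Loo-Riegelman deconvolution and its exact inverse
    (convolution), Levy-plot time scaling, the classical two-step linear
    level-A correlation with FDA percent-prediction-error validation, and a
    one-step differential-equation IVIVC with logistic cut-off, extent and
    time-scaling link functions fitted simultaneously across formulations.
    Includes synthetic-data generators emulating cross-over bioequivalence
    trials and replicated flow-through-cell dissolution runs so the whole
    pipeline can be exercised and tested without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
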