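Package: gastrosim
Title: Gastric Emptying with Viscosity-Dependent Secretion and Duodenal-Brake Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates gastric emptying of liquid meals with a stirred gastric
    compartment coupled to a one-dimensional advective small intestine.
    Gastric secretion responds to chyme viscosity through a power-law
    rheology, and intestinal nutrient absorption gates the emptying rate via
    a duodenal-brake switch (logical or smoothed).  The package provides the
    forward simulator, bounded nonlinear least-squares parameter estimation,
    AIC-based selection among competing emptying-rate hypotheses, normalized
    finite-difference sensitivity analysis, noise-injection Monte-Carlo
    uncertainty quantification, and a synthetic-data generator emulating
    published gastric-content and viscosity time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    minpack.lm,
    lhs,
    readr,
    yaml,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
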