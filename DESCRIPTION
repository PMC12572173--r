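Package: mrtriad
Title: Three-Stage Mendelian Randomisation Screen with Mediation and
    Colocalisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation (MR) screens that
    trace an anthropometric exposure through circulating metabolites to a
    binary disease outcome. Implements summary-statistic harmonisation with
    palindromic-variant handling, LD clumping and proxy search against a
    genotype reference panel, the standard univariable MR estimators
    (inverse-variance weighted, MR-Egger, median, mode, maximum likelihood)
    with the full sensitivity battery (Cochran's Q, Egger intercept,
    leave-one-out, bidirectional MR), enumeration colocalisation with
    approximate Bayes factors and locus-scaled priors, and mediation by both
    the multivariable-MR difference method and the product-of-coefficients
    method. A seeded synthetic-data generator produces reference panels and
    exposure-metabolite-outcome summary-statistic triads with known ground
    truth so every stage can be exercised without consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
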