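Package: mggp
Title: Multi-Group Gaussian Process Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gaussian process regression over the product of a continuous input
    space and a finite set of groups. Provides nonseparable Gneiting-class
    multi-group covariance functions (squared-exponential, Matern and
    exponential families) indexed by a group-similarity scale, separable and
    hierarchical baselines, spectral and eigenvalue certificates of positive
    definiteness, collapsed-likelihood regression with maximum-likelihood and
    fully Bayesian inference, posterior prediction, and simulation drivers
    for parameter-recovery and held-out prediction studies on grouped data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    coda,
    readr
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    pracma,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
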