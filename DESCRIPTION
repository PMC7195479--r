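Package: divnorm
Title: Dynamic Divisive Normalization Models of Perceptual Evidence Accumulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and maximum-likelihood fitting of evidence-accumulation
    models for the fixed-grid auditory clicks task. Implements a dynamic
    divisive-normalization circuit (two excitatory pools divisively inhibited
    by a shared gain unit), its analytic per-click integration kernel and
    choice likelihood, together with drift-diffusion-family competitors (basic
    DDM, leaky/unstable accumulator, and a bounded accumulator with per-side
    sensory adaptation solved by density propagation). Provides model-free
    integration-kernel estimation by logistic regression, kernel-shape
    classification, psychometric curves, multi-start maximum-likelihood
    fitting, AIC/BIC model comparison, and synthetic cohorts reproducing the
    four kernel phenotypes (primacy, bump, flat, recency).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
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
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
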