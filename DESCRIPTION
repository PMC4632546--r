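Package: crypticallee
Title: Hierarchical Bayesian Analysis of Density-Dependent Fertilization in
    Freshwater Mussels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect component Allee effects in the fertilization
    success of sessile stream organisms when spatial scale and flow
    heterogeneity can mask them. Implements a two-level binomial-logit
    hierarchical model with cross-level structure, density-by-flow
    interactions, nested date-within-year and population random effects, and
    an observation-level overdispersion term; posterior inference by adaptive
    Metropolis-within-Gibbs sampling with split-chain R-hat diagnostics,
    posterior predictive Bayesian p-values, credible-interval and
    sign-probability summaries, and percentile-conditioned prediction curves.
    Includes a study-design simulator that generates per-female fertilization
    counts either from the fitted-model structure or from a mechanistic
    sperm-dilution scene in which positive density dependence is visible only
    locally under slow, shallow flow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
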