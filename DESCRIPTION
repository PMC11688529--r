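Package: ouregime
Title: Multi-Regime Ornstein-Uhlenbeck Trait Evolution and Phylogenetic
    Regression for COX-Linked Genome Downsizing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-phylogenetics pipeline linking a discrete
    molecular character (the mitochondrial COX helix-3 mutation, states
    LS/CC/CS) to continuous trait downsizing (1C genome size and mean
    chromosome size in Lentibulariaceae). Provides maximum-likelihood
    marginal ancestral sequence reconstruction under JC/K2P/HKY models
    with discrete-Gamma rate heterogeneity and BIC model selection,
    regime painting of branches from node states, phylogenetic
    generalized least squares with Brownian-motion and
    Ornstein-Uhlenbeck error structures, the seven-model
    BM1/BMS/OU1/OUM/OUMV/OUMA/OUMVA trait-evolution comparison with
    Akaike weights, parametric bootstrap of regime optima with
    Mann-Whitney comparisons, and a synthetic-study generator (Yule
    trees, Markov regime histories, sequence evolution, multi-regime OU
    traits) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    knitr,
    Matrix,
    nlme,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
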