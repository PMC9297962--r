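Package: assemblage
Title: Joint Simulation and Inference of Community Assembly Across
    Abundance, Genetic Diversity and Trait Axes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hierarchical simulator of ecological community assembly that
    jointly generates species abundances, community-scale population-genetic
    diversity (per-species nucleotide diversity from rescaled coalescent
    models) and trait distributions under neutral, environmental-filtering
    and competition dynamics, together with a supervised-learning inference
    layer (feature selection, random-forest classification of assembly
    models, parameter regression with quantile prediction intervals, and
    posterior predictive checks) for fitting the model to observed
    community data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    e1071,
    jsonlite,
    ranger,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
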