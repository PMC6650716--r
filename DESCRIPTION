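Package: hsmnet
Title: Hierarchical Social Modularity Inference from Covisit Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers hierarchically nested social structure from records of
    social units visiting a shared resource hotspot (such as gorilla groups
    and solitary males visiting a forest clearing). Computes simple-ratio
    and binomial-probability association indices from unit-by-day presence
    matrices, builds data-stream permutation and parametric null models,
    detects social tiers from UPGMA dendrograms via a bifurcation-rate
    change-point (knot) statistic, runs Louvain modularity with a
    resolution-parameter sweep to find multiple organisational scales, fits
    the scaling ratio of social-unit sizes across tiers, and tests kinship
    and cross-method consistency with dyadic logistic regressions. Includes
    a synthetic visit-stream generator with planted two-tier structure for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    mclust,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
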