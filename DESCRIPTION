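Package: inferatlas
Title: Semantic-Atlas Mining of Inferiority-Feeling Microblog Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for mining the causes of inferiority feelings
    from microblog posts. Implements ontological attribute-keyword filtering
    (a boolean conjunction over six synonym groups), a marketing-account
    follower filter, an SVM relevance classifier over mean word-vector
    features, skip-gram word-embedding training, semantic-primitive
    extraction by the combined semantic-frequency / semantic-active-index
    (SF-SAI) score, a two-dimensional semantic atlas (t-SNE projection,
    relative pairwise distances, distance statistics, kernel-density
    surface, and a closeness rule), and theme-coding consistency analysis
    with Cohen's kappa. Ships a synthetic corpus generator with planted
    ground truth so the whole pipeline is exercisable end to end without
    access to the original social-media data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    readr,
    withr,
    rlang,
    ggplot2,
    MASS,
    e1071,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
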