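Package: tipclust
Title: Bayesian Nonparametric Clustering with the Table Invitation Prior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Distance-dependent Bayesian nonparametric clustering of
    gene-expression samples (or any vector-variate subjects) with the Table
    Invitation Prior: a random host subject invites its most similar
    neighbours to a new cluster, with the invitation size driven by
    change-point detection on the host's sorted pairwise distances. Includes
    a collapsed Gibbs sampler with a conjugate Normal-Inverse-Wishart
    likelihood, Ewens-Pitman Attraction and Chinese Restaurant Process
    baseline samplers with West's posterior for the mass parameter,
    posterior-similarity-matrix summaries with PEAR consensus selection,
    a maximum-weight spanning-tree co-clustering graph, a Gaussian /
    inverse-Wishart simulation generator, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
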