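Package: famres
Title: Hierarchical Family-Resemblance Models of Perceptual Categorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Bayesian nonparametric models of perceptual categorization in
    which dimensional biases emerge from learned expectations about cluster
    covariance structure. Implements a hierarchical Dirichlet-process mixture
    in which items are partitioned into Gaussian clusters by a Chinese
    restaurant process and cluster covariances are shared across learning
    contexts through a hierarchical Chinese restaurant process over
    inverse-Wishart covariance components. Provides Gibbs sampling for the
    full hierarchy, a Rao-Blackwellized particle filter for the trained
    fixed-component approximation, exact posterior computation by partition
    enumeration for small stimulus sets, the classic rational model of
    categorization as a baseline, a library of category-learning task
    fixtures (Shepard-Hovland-Jenkins problems, condensation versus
    filtration, biconditional discrimination, Garner filtering, free
    classification), similarity-field and Minkowski-metric diagnostics, and a
    desk-scale analysis of category dispersion statistics on feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
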