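Package: breedplay
Title: Phylogenetic Comparative Analysis of Human-Directed Play Behaviour
    Across Dog Breeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of human-directed play
    behaviour across dog breeds on a breed phylogeny. Implements maximum
    likelihood ancestral state reconstruction for discrete breed function
    (equal-rates Mk model via the pruning algorithm, with marginal scaled
    likelihoods at every node) and for a continuous play score (Brownian
    motion with Pagel's lambda and 95% confidence intervals), and a
    Bayesian phylogenetic mixed model that partitions among-breed variance
    into common-ancestry and gene-flow components using two relatedness
    matrices, breed-group fixed effects and known measurement-error
    variances, with DIC model comparison and posterior group contrasts.
    A synthetic-data module generates breed trees, group labels, latent
    trait values with dual covariance structure and individual ordinal
    scores with known ground truth, so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    phytools,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
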