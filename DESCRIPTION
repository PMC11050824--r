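Package: lsirt
Title: Latent Space Item Response Modeling for Binary Assessment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian estimation and exploration of the latent space item
    response model, a Rasch model augmented with person and item positions in
    a shared low-dimensional metric space.  Person-item distances absorb
    conditional dependence (residual person-item interactions) left over after
    the main ability and item effects, and a spike-and-slab prior on the
    distance weight provides built-in model selection against the plain Rasch
    model.  The package includes adaptive Metropolis-within-Gibbs samplers
    written in C++, split R-hat convergence diagnostics, Procrustes alignment
    of posterior position draws, interaction-map analytics (item distance
    matrices, item cluster summaries, person-cluster distances,
    perceived-difficulty intervals, covariate overlays, personalized
    feedback), seeded synthetic-data generators for recovery studies, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    mclust,
    MASS
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
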