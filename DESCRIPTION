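Package: speleodiv
Title: State-Dependent Diversification and Range-Size Analyses for Cave Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative phylogenetic tests of whether obligate cave life is an
    evolutionary dead-end. Implements pruning-algorithm likelihoods for
    state-dependent speciation-extinction models (BiSSE, GeoSSE and a
    hidden-state HiSSE family) with per-state sampling fractions, constraint
    masks and marginal ancestral states; Bayesian inference by univariate
    slice-sampling MCMC with exponential priors, posterior hypothesis
    probabilities, harmonic-mean Bayes factors and AIC weights; Felsenstein's
    threshold model for the correlation between a binary habitat trait's
    liability and a continuous trait such as log10 geographic range size;
    posterior-predictive model-adequacy diagnostics (tip-state count
    chi-squared test and the sum of sister-clade differences); and seeded
    generators of synthetic trees, characters and range tables with known
    ground truth. Trees are ape "phylo" objects throughout.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
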