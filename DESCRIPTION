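Package: netcoal
Title: Bayesian Phylogenetic Network Inference Under the Multispecies
    Network Coalescent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers reticulate species phylogenies (phylogenetic networks)
    from collections of estimated rooted gene-tree topologies under the
    multispecies network coalescent. Provides an exact gene-tree-topology
    probability mass function on networks with inheritance probabilities,
    Poisson/exponential network priors, a seven-move reversible-jump
    Metropolis-Hastings sampler with 95 percent credible-set
    summarization, a coalescent simulator on networks for validation and
    synthetic-data generation (including sequence simulation and
    bootstrap gene-tree re-estimation), and extended-Newick input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    ape,
    phangorn,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
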