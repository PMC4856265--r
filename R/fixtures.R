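# The three 7-taxon model networks used by the simulation study: one
# designated outgroup (OUT), 1 / 2 / 3 reticulations among the ingroup
# taxa, branch lengths ranging from short (0.5 coalescent units) to
# longer (1.5), and fixed inheritance probabilities. The same strings are
# shipped as inst/extdata/model_networks.enewick.

MODEL_NETWORKS <- c(
  m1 = paste0("((((A:1.0,B:1.0):0.8,((C:0.6)#H1:0.6::0.7,D:1.2):0.6):0.7,",
              "((#H1:0.5::0.3,E:1.1):0.5,F:1.5):0.9):1.2,OUT:1.5);"),
  m2 = paste0("((((A:1.0,(B:0.5)#H2:0.5::0.8):0.8,((C:0.6)#H1:0.6::0.7,",
              "(#H2:0.6::0.2,D:0.6):0.6):0.6):0.7,",
              "((#H1:0.5::0.3,E:1.1):0.5,F:1.5):0.9):1.2,OUT:1.5);"),
  m3 = paste0("((((A:1.0,(B:0.5)#H2:0.5::0.8):0.8,((C:0.6)#H1:0.6::0.7,",
              "(#H2:0.6::0.2,D:0.6):0.6):0.6):0.7,",
              "((#H1:0.5::0.3,(E:0.5)#H3:0.6::0.75):0.5,",
              "(#H3:0.6::0.25,F:0.9):0.6):0.9):1.2,OUT:1.5);"))

#' The three model networks of the simulation study
#'
#' Deterministic construction of the package's 7-taxon fixture networks
#' (taxa A-F plus the outgroup OUT) with 1, 2 and 3 reticulation nodes,
#' branch lengths between 0.5 and 1.5 coalescent units, and fixed
#' inheritance probabilities. These are the generating networks for the
#' synthetic recovery experiments; the same extended-Newick strings ship
#' in `inst/extdata/model_networks.enewick`.
#'
#' @return named list of three [PhyloNetwork-class] objects (`m1`, `m2`,
#'   `m3`).
#' @export
modelNetworkSuite <- function() {
  lapply(as.list(MODEL_NETWORKS), parseENewick)
}
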