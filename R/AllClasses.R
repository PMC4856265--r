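#' @import methods
NULL

#' Phylogenetic network
#'
#' A rooted binary phylogenetic network: a directed acyclic graph with a
#' single root (in-degree 0, out-degree 2), labeled leaves (in-degree 1,
#' out-degree 0), internal tree nodes (in-degree 1, out-degree 2) and
#' reticulation nodes (in-degree 2, out-degree 1). Branch lengths are in
#' coalescent units (generations divided by effective population size).
#' Each in-edge of a reticulation node carries an inheritance probability;
#' the two probabilities at a node sum to 1.
#'
#' @slot edge integer matrix with columns (tail, head); node ids are opaque.
#' @slot len numeric branch lengths, one per edge row.
#' @slot gamma numeric inheritance probabilities, one per edge row; `NA`
#'   unless the edge points into a reticulation node.
#' @slot label named character vector of taxon names, names are leaf node
#'   ids.
#' @slot root integer id of the root node.
#'
#' @seealso [parseENewick()], [writeENewick()], [validateNetwork()],
#'   [topologyKey()]
#' @export
setClass("PhyloNetwork",
         representation(edge = "matrix", len = "numeric", gamma = "numeric",
                        label = "character", root = "integer"))

setValidity("PhyloNetwork", function(object) {
  viol <- nw_validate(as_nw(object))
  if (nrow(viol) == 0L) TRUE
  else paste(sprintf("[%s] %s", viol$kind, viol$detail), collapse = "; ")
})

as_nw <- function(x) {
  if (is(x, "PhyloNetwork"))
    return(new_nw(x@edge, x@len, x@gamma, x@label, x@root))
  x
}

nw_to_s4 <- function(nw, check = TRUE) {
  obj <- new("PhyloNetwork", edge = nw$edge, len = nw$len, gamma = nw$gamma,
             label = nw$label, root = nw$root)
  if (check) validObject(obj)
  obj
}

#' Multi-locus gene-tree data
#'
#' Holds, for `m` independent loci, a multiset of rooted gene-tree
#' topologies per locus (for example 100 bootstrap trees), after mapping
#' allele labels to species through the taxon map. Topologies are pooled
#' across loci and deduplicated: `topologies` stores one encoded
#' representative per distinct topology (named by canonical key) and each
#' locus stores integer multiplicities over those keys, so the likelihood
#' evaluates each distinct topology exactly once.
#'
#' @slot topologies named list of encoded rooted topologies (internal
#'   representation; see [geneTreeProb()]).
#' @slot lociWeights list of named numeric vectors, one per locus: counts
#'   of each topology key within the locus's multiset.
#' @slot taxonMap named character vector mapping allele labels to species.
#' @slot species character vector of species names occurring in the data.
#' @export
setClass("GeneTreeData",
         representation(topologies = "list", lociWeights = "list",
                        taxonMap = "character", species = "character"))

setValidity("GeneTreeData", function(object) {
  if (length(object@lociWeights) < 1L) return("at least one locus is required")
  for (i in seq_along(object@lociWeights)) {
    w <- object@lociWeights[[i]]
    if (length(w) < 1L || any(w <= 0))
      return(sprintf("locus %d has an empty or non-positive tree multiset", i))
    if (!all(names(w) %in% names(object@topologies)))
      return(sprintf("locus %d references an unknown topology key", i))
  }
  TRUE
})

#' Posterior sample of networks and inheritance probabilities
#'
#' The thinned, post-burn-in record of a Metropolis-Hastings run: one row
#' per stored state with the canonical topology key, the extended-Newick
#' serialization (branch lengths and inheritance probabilities included),
#' the log-likelihood and log-prior, plus per-move proposal and acceptance
#' counts for diagnostics.
#'
#' @slot records data.frame with columns `iteration`, `key`, `newick`,
#'   `logLik`, `logPrior`, `move`, `accepted`.
#' @slot moveStats data.frame with per-move `proposed` and `accepted`
#'   counts over the whole run (burn-in included).
#' @slot config list; the fully resolved run configuration.
#' @export
setClass("SampleChain",
         representation(records = "data.frame", moveStats = "data.frame",
                        config = "list"))
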