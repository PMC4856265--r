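# User-facing network operations.

#' Parse an extended-Newick string into a PhyloNetwork
#'
#' Reticulation nodes appear twice with a shared `#H<k>` tag; the per-edge
#' field layout is `:length:support:gamma` where the third field is the
#' inheritance probability of that edge (the support field is ignored).
#' Missing branch lengths default to 1 coalescent unit; missing inheritance
#' probabilities to 0.5. Trees are the zero-reticulation special case.
#'
#' @param text a single extended-Newick string, terminated by `;`.
#' @return a validated [PhyloNetwork-class] object.
#' @examples
#' net <- parseENewick("((A:1,(B:0.5)#H1:0.5::0.3):1,(#H1:0.5::0.7,C:1):1);")
#' nReticulations(net)
#' @export
parseENewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  nw_to_s4(parse_enewick_nw(text))
}

#' Read networks from an extended-Newick file
#'
#' One network per non-empty line; lines starting with `#` are skipped.
#'
#' @param file path to a UTF-8 text file.
#' @return a list of [PhyloNetwork-class] objects.
#' @export
readENewick <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop(sprintf("no networks found in '%s'", file))
  lapply(lines, parseENewick)
}

#' Serialize a network to extended Newick
#'
#' Child order is canonical (sorted by the leaf cluster under each child),
#' so the output is deterministic; the result is parseable by
#' [parseENewick()] and round-trips to an isomorphic network.
#'
#' @param net a [PhyloNetwork-class] object.
#' @param lengths include branch lengths.
#' @param gammas include inheritance probabilities (third colon field).
#' @return a single extended-Newick string.
#' @export
writeENewick <- function(net, lengths = TRUE, gammas = TRUE) {
  write_enewick_nw(as_nw(net), lengths = lengths, gammas = gammas)
}

#' Validate a candidate network
#'
#' Accepts arbitrary candidate graphs (for example the raw output of a
#' proposal move) and reports every violated condition of the phylogenetic
#' network definition: directed cycles, parallel edges (same tail and
#' head), more than one in-degree-0 node, degree-class violations, and
#' negative branch lengths. An empty result means the candidate is a valid
#' network; the sampler's prior assigns probability 0 to any candidate
#' with a non-empty result.
#'
#' @param net a [PhyloNetwork-class] object or an equivalent list.
#' @return a data.frame with columns `kind` (one of `cycle`,
#'   `parallel-edge`, `multiple-roots`, `degree-violation`,
#'   `negative-length`) and `detail`.
#' @export
validateNetwork <- function(net) nw_validate(as_nw(net))

#' Canonical topology key of a network
#'
#' Two networks receive the same key exactly when their leaf-labeled
#' topologies are isomorphic, ignoring branch lengths and inheritance
#' probabilities. Used to count distinct topologies in posterior samples
#' and credible sets.
#'
#' @param net a [PhyloNetwork-class] object.
#' @return a character scalar.
#' @export
topologyKey <- function(net) {
  nw <- as_nw(net)
  viol <- nw_validate(nw)
  if (nrow(viol))
    stop("topologyKey requires a valid network: ", viol$kind[1])
  topology_key_nw(nw)
}

#' Count phylogenetic network topologies
#'
#' The number `T[n,m]` of distinct rooted binary network topologies with
#' `n` labeled leaves and `m` reticulation nodes, computed by exhaustive
#' generation and canonical-key deduplication. Enumeration is guarded to
#' `n <= 5`, `m <= 2`. Outside the guard, mode `"auto"` returns a
#' combinatorial surrogate -- the tree count `(2n-3)!!` times, per added
#' reticulation, the number of ordered attachment-edge pairs -- which
#' tracks the exact counts within a small factor and keeps the prior's
#' reticulation-count classes comparably weighted; mode `"constant"`
#' returns 1 (rescaling class weights only) and `"enumerate"` raises an
#' error. For trees, `countTopologies(n, 0) == (2n-3)!!`.
#'
#' @param n leaf count, `n >= 2`.
#' @param m reticulation count, `m >= 0`.
#' @param mode `"auto"` (enumerate within the guard, else 1),
#'   `"enumerate"`, or `"constant"`.
#' @return a positive number.
#' @examples
#' countTopologies(3, 0)  # 3 rooted binary trees
#' countTopologies(5, 0)  # 105
#' @export
countTopologies <- function(n, m, mode = c("auto", "enumerate", "constant")) {
  count_topologies_impl(as.integer(n), as.integer(m), match.arg(mode))
}

#' Enumerate all network topologies on a label set
#'
#' Exhaustively generates every rooted binary network topology with the
#' given leaf labels and exactly `m` reticulation nodes (deduplicated by
#' canonical key). Intended for small instances; the same guard as
#' [countTopologies()] applies.
#'
#' @param labels character vector of leaf names (length 2..5).
#' @param m number of reticulation nodes (0..2).
#' @return a list of [PhyloNetwork-class] objects.
#' @export
enumerateNetworks <- function(labels, m = 0L) {
  stopifnot(length(labels) >= 2L, length(labels) <= 5L, m <= 2L)
  lapply(enumerate_networks_nw(labels, as.integer(m)), nw_to_s4, check = FALSE)
}

# ---- accessors -------------------------------------------------------------

#' @describeIn PhyloNetwork-accessors taxon names at the leaves
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @describeIn PhyloNetwork-accessors number of reticulation nodes
#' @export
setGeneric("nReticulations", function(x) standardGeneric("nReticulations"))

#' @describeIn PhyloNetwork-accessors branch lengths (coalescent units)
#' @export
setGeneric("branchLengths", function(x) standardGeneric("branchLengths"))

#' @describeIn PhyloNetwork-accessors per-reticulation inheritance
#'   probabilities
#' @export
setGeneric("inheritance", function(x) standardGeneric("inheritance"))

#' Accessors for PhyloNetwork objects
#'
#' @param x a [PhyloNetwork-class] object.
#' @name PhyloNetwork-accessors
#' @aliases taxa nReticulations branchLengths inheritance
NULL

#' @rdname PhyloNetwork-accessors
#' @export
setMethod("taxa", "PhyloNetwork", function(x) sort(unname(x@label)))

#' @rdname PhyloNetwork-accessors
#' @export
setMethod("nReticulations", "PhyloNetwork",
          function(x) length(nw_retic_nodes(as_nw(x))))

#' @rdname PhyloNetwork-accessors
#' @export
setMethod("branchLengths", "PhyloNetwork", function(x) x@len)

#' @rdname PhyloNetwork-accessors
#' @export
setMethod("inheritance", "PhyloNetwork", function(x) {
  nw <- as_nw(x)
  nodes <- nw_retic_nodes(nw)
  if (!length(nodes))
    return(data.frame(node = integer(0), parent = integer(0),
                      gamma = numeric(0)))
  do.call(rbind, lapply(nodes, function(v) {
    ein <- which(nw$edge[, 2] == v)
    data.frame(node = v, parent = nw$edge[ein, 1], gamma = nw$gamma[ein])
  }))
})

setMethod("show", "PhyloNetwork", function(object) {
  nw <- as_nw(object)
  cat(sprintf("PhyloNetwork: %d taxa, %d reticulation node(s)\n",
              nw_ntaxa(nw), length(nw_retic_nodes(nw))))
  cat(" ", write_enewick_nw(nw), "\n", sep = "")
})

setMethod("show", "GeneTreeData", function(object) {
  cat(sprintf("GeneTreeData: %d loci, %d distinct topologies, %d species\n",
              length(object@lociWeights), length(object@topologies),
              length(object@species)))
})

setMethod("show", "SampleChain", function(object) {
  cat(sprintf("SampleChain: %d stored samples\n", nrow(object@records)))
  if (nrow(object@records)) {
    cat(sprintf("  log-posterior range: [%.3f, %.3f]\n",
                min(object@records$logLik + object@records$logPrior),
                max(object@records$logLik + object@records$logPrior)))
    cat(sprintf("  distinct topologies: %d\n",
                length(unique(object@records$key))))
  }
})
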