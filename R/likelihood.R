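# Gene-tree-topology likelihood under the multispecies network coalescent.

#' Coalescent lineage transition probability
#'
#' Probability that `u` lineages entering a population branch of length
#' `t` coalescent units leave it as `v` lineages (Tavare's closed form:
#' an alternating sum of exponentials with rising/falling factorial
#' coefficients). `t = Inf` denotes the branch above the root, where all
#' lineages must coalesce.
#'
#' @param u number of lineages entering the branch (bottom).
#' @param v number of lineages leaving the branch (top), `1 <= v <= u`.
#' @param t branch length in coalescent units, `>= 0` or `Inf`.
#' @return a probability; for fixed `u` and `t` the values sum to 1 over
#'   `v = 1..u`.
#' @examples
#' coalescenceProb(2, 1, 1)  # 1 - exp(-1)
#' @export
coalescenceProb <- function(u, v, t) {
  stopifnot(length(u) == 1L, length(v) == 1L, length(t) == 1L)
  if (v < 1 || v > u) stop("coalescenceProb requires 1 <= v <= u")
  if (t < 0) stop("coalescenceProb requires t >= 0")
  if (u <= 1 || t == 0) return(as.numeric(v == u))
  if (!is.finite(t)) return(as.numeric(v == 1))
  k <- v:u
  terms <- vapply(k, function(kk) {
    prod1 <- prod((v + 0:(kk - 1)) * (u - 0:(kk - 1)) / (u + 0:(kk - 1)))
    (-1)^(kk - v) * exp(-kk * (kk - 1) * t / 2) *
      (2 * kk - 1) / (v + kk - 1) * prod1 /
      (factorial(v) * factorial(kk - v))
  }, 0)
  min(max(sum(terms), 0), 1)
}

# species indices of the network leaves for a given level order; the
# leaf labeling never changes during a run, so callers can compute this
# once and reuse it
nw_leaf_species <- function(nw, levels) {
  sp <- match(unname(nw$label), levels)
  if (anyNA(sp))
    stop("network contains a species absent from the expected species set")
  list(ids = as.integer(names(nw$label)), species = as.integer(sp))
}

# encode a rooted binary gene tree (ape phylo) as a parent vector over
# nodes 1..2L-1 (leaves first) plus the species name of each leaf
encode_gene_tree <- function(phy, map = NULL) {
  if (!inherits(phy, "phylo")) stop("gene trees must be 'phylo' objects")
  nt <- length(phy$tip.label)
  if (nt == 1L) {
    parent <- 0L
    species <- phy$tip.label
    if (!is.null(map)) {
      if (!(species %in% names(map)))
        stop(sprintf("allele '%s' is missing from the taxon map", species))
      species <- unname(map[species])
    }
    return(list(parent = parent, species = species))
  }
  if (phy$Nnode != nt - 1L)
    stop("gene trees must be rooted and binary")
  parent <- integer(nt + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  species <- phy$tip.label
  if (!is.null(map)) {
    miss <- setdiff(species, names(map))
    if (length(miss))
      stop(sprintf("allele '%s' is missing from the taxon map", miss[1]))
    species <- unname(map[species])
  }
  list(parent = parent, species = species)
}

# attach integer species indices for a given species level order
prep_topos <- function(topologies, levels) {
  lapply(topologies, function(tp) {
    ls <- match(tp$species, levels)
    if (anyNA(ls))
      stop(sprintf("gene-tree species '%s' is not a leaf of the network",
                   tp$species[is.na(ls)][1]))
    list(parent = tp$parent, leafSpecies = as.integer(ls))
  })
}

# low-level evaluation: masses of prepared topologies under a nw
nw_masses <- function(nw, prepped, levels, leaves = NULL) {
  if (is.null(leaves)) leaves <- nw_leaf_species(nw, levels)
  cpp_msnc_masses(nw$edge, nw$len, nw$gamma, leaves$ids, leaves$species,
                  nw$root, prepped)
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L)
    return(ape::read.tree(text = tree))
  stop("expected a 'phylo' object or a Newick string")
}

#' Probability mass of a gene-tree topology under the MSNC
#'
#' Exact probability of observing the rooted gene-tree topology `tree`
#' for one non-recombining locus, given the species network, its branch
#' lengths (coalescent units) and inheritance probabilities. The
#' computation sums over all assignments of lineages to parent edges at
#' reticulation nodes (weighted by gamma and 1 - gamma) and over all
#' coalescent histories compatible with the topology. Over all rooted
#' binary topologies on the same leaf set the masses sum to 1; on a tree
#' (zero reticulations) the value reduces to the multispecies-coalescent
#' mass.
#'
#' @param net a [PhyloNetwork-class] object.
#' @param tree a rooted binary gene tree: `phylo` object or Newick string.
#'   Tip labels are allele names, mapped to species via `taxonMap`.
#' @param taxonMap optional named character vector, allele -> species;
#'   identity when `NULL` (tip labels are species names).
#' @return a probability in `[0, 1]`.
#' @examples
#' net <- parseENewick("((A:1,B:1):1,C:1);")
#' geneTreeProb(net, "((A,B),C);")  # 1 - (2/3) * exp(-1)
#' @export
geneTreeProb <- function(net, tree, taxonMap = NULL) {
  nw <- as_nw(net)
  levels <- sort(unname(nw$label))
  enc <- encode_gene_tree(as_phylo_tree(tree), taxonMap)
  nw_masses(nw, prep_topos(list(enc), levels), levels)[1]
}

#' Likelihood of one locus from a multiset of gene-tree estimates
#'
#' Gene-tree uncertainty is handled by averaging: the locus likelihood is
#' the unweighted arithmetic mean of [geneTreeProb()] over the locus's
#' multiset of topology estimates (for example 100 bootstrap trees).
#' Duplicate topologies are collapsed and weighted, which leaves the
#' value unchanged.
#'
#' @param net a [PhyloNetwork-class] object.
#' @param trees list of rooted gene trees (`phylo` or Newick strings), or
#'   an `ape::multiPhylo`.
#' @param taxonMap optional named character vector, allele -> species.
#' @return a probability in `[0, 1]`.
#' @export
locusLikelihood <- function(net, trees, taxonMap = NULL) {
  if (inherits(trees, "multiPhylo")) trees <- unclass(trees)
  if (inherits(trees, "phylo")) trees <- list(trees)
  stopifnot(length(trees) >= 1L)
  nw <- as_nw(net)
  levels <- sort(unname(nw$label))
  encs <- lapply(trees, function(tr) encode_gene_tree(as_phylo_tree(tr), taxonMap))
  # the key must cover both shape and leaf-species assignment
  keys <- vapply(encs, function(e)
    paste(paste(e$parent, collapse = ","), paste(e$species, collapse = ","),
          sep = "|"), "")
  first <- !duplicated(keys)
  w <- as.numeric(table(factor(keys, levels = keys[first])))
  m <- nw_masses(nw, prep_topos(encs[first], levels), levels)
  sum(w * m) / sum(w)
}

#' Multi-locus log-likelihood of gene-tree data
#'
#' The log of the product over loci of [locusLikelihood()]: the
#' posterior's data term. Distinct topologies are pooled across loci and
#' each is evaluated once, then recombined with per-locus multiplicities;
#' the result equals the uncached computation. A locus whose likelihood
#' underflows to 0 yields `-Inf` (the state is rejectable, not an error).
#'
#' @param net a [PhyloNetwork-class] object.
#' @param data a [GeneTreeData-class] object (see [readGeneTrees()],
#'   [makeGeneTreeData()]).
#' @return a log-probability, possibly `-Inf`.
#' @export
dataLogLik <- function(net, data) {
  stopifnot(is(data, "GeneTreeData"))
  nw <- as_nw(net)
  levels <- sort(unname(nw$label))
  prepped <- prep_topos(data@topologies, levels)
  masses <- nw_masses(nw, prepped, levels)
  names(masses) <- names(data@topologies)
  ll <- 0
  for (w in data@lociWeights) {
    lik <- sum(w * masses[names(w)]) / sum(w)
    if (!is.finite(lik) || lik <= 0) return(-Inf)
    ll <- ll + log(lik)
  }
  ll
}

# fast path used inside the sampler: weight matrix W (loci x topologies)
# and totals precomputed once
data_loglik_fast <- function(nw, prepped, levels, W, Wtot, leaves = NULL) {
  masses <- nw_masses(nw, prepped, levels, leaves)
  lik <- as.numeric(W %*% masses) / Wtot
  if (any(lik <= 0) || any(!is.finite(lik))) return(-Inf)
  sum(log(lik))
}
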