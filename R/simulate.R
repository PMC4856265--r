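# Forward simulation under the multispecies network coalescent, and
# sequence simulation along the resulting gene trees.
#
# The simulator is the package's Monte-Carlo oracle for the likelihood
# (empirical topology frequencies must match geneTreeProb) and the
# synthetic-data factory for the recovery experiments.

#' Simulation configuration
#'
#' @param loci number of independent loci to simulate.
#' @param samplesPerSpecies named integer vector: lineages sampled per
#'   species; species absent from the vector get 1.
#' @param theta population mutation rate used to convert coalescent units
#'   to expected substitutions per site (a branch of length `t`
#'   coalescent units gets `theta / 2 * t` expected substitutions).
#' @param seqLength sites per locus.
#' @param model `"JC"` or `"GTR"`; for GTR supply `Q` (6 exchangeability
#'   rates, order AC AG AT CG CT GT) and `bf` (4 base frequencies).
#' @param Q,bf GTR parameters (ignored under JC).
#' @param bootstrapReps bootstrap replicates per locus in
#'   [estimateGeneTrees()].
#' @return list of class `sim_config`.
#' @export
simConfig <- function(loci = 100L, samplesPerSpecies = NULL, theta = 0.036,
                      seqLength = 1000L, model = c("JC", "GTR"), Q = NULL,
                      bf = NULL, bootstrapReps = 100L) {
  model <- match.arg(model)
  stopifnot(loci >= 1L, theta > 0, seqLength >= 1L, bootstrapReps >= 1L)
  if (model == "GTR") {
    if (is.null(Q) || is.null(bf) || length(Q) != 6L || length(bf) != 4L ||
        any(Q <= 0) || any(bf <= 0) || abs(sum(bf) - 1) > 1e-8)
      stop("GTR requires 6 positive rates and 4 base frequencies summing to 1")
  }
  structure(list(loci = as.integer(loci),
                 samplesPerSpecies = samplesPerSpecies, theta = theta,
                 seqLength = as.integer(seqLength), model = model, Q = Q,
                 bf = bf, bootstrapReps = as.integer(bootstrapReps)),
            class = "sim_config")
}

# allele labels for a species: the species name itself for a single
# sample, species_1, species_2, ... otherwise
allele_names <- function(species, k) {
  if (k == 1L) species else paste(species, seq_len(k), sep = "_")
}

#' Simulate one gene tree under the MSNC
#'
#' Backward-in-time coalescent on the network: within every branch, each
#' pair of lineages coalesces at rate 1 per coalescent unit; at a
#' reticulation node every surviving lineage independently tracks the
#' designated parent edge with that edge's inheritance probability; the
#' lineages that reach the root coalesce in the infinite root branch.
#' Branch lengths of the returned gene tree are in coalescent units.
#'
#' @param net a [PhyloNetwork-class] object.
#' @param samplesPerSpecies named integer vector (default 1 per species).
#' @return a rooted `phylo` with allele tip labels.
#' @export
simulateGeneTree <- function(net, samplesPerSpecies = NULL) {
  nw <- as_nw(net)
  sim_gene_tree_nw(nw, samplesPerSpecies)
}

sim_gene_tree_nw <- function(nw, samplesPerSpecies = NULL) {
  species <- unname(nw$label)
  nsamp <- structure(rep(1L, length(species)), names = species)
  if (!is.null(samplesPerSpecies)) {
    bad <- setdiff(names(samplesPerSpecies), species)
    if (length(bad))
      stop(sprintf("sampled species '%s' is not a network leaf", bad[1]))
    nsamp[names(samplesPerSpecies)] <- as.integer(samplesPerSpecies)
  }
  ntips <- sum(nsamp)
  stopifnot(ntips >= 1L)

  # growing gene tree: tips 1..ntips, internal nodes appended
  tip_lab <- character(ntips)
  par_edges <- list()        # list of c(child, parent is implicit later)
  # lineage: list(node = gene-tree node id, pend = accumulated length)
  edge_child <- integer(0); edge_parent <- integer(0); edge_len <- numeric(0)
  next_node <- ntips
  tip_i <- 0L

  # coalesce lineage set within a branch of length t; returns lineages
  run_branch <- function(lins, t) {
    k <- length(lins)
    s <- 0
    while (k >= 2L) {
      tau <- stats::rexp(1, k * (k - 1) / 2)
      if (s + tau > t) break
      s <- s + tau
      for (j in seq_len(k)) lins[[j]]$pend <- lins[[j]]$pend + tau
      pick <- sample.int(k, 2L)
      a <- lins[[pick[1]]]; b <- lins[[pick[2]]]
      next_node <<- next_node + 1L
      edge_child <<- c(edge_child, a$node, b$node)
      edge_parent <<- c(edge_parent, next_node, next_node)
      edge_len <<- c(edge_len, a$pend, b$pend)
      lins <- lins[-pick]
      lins[[length(lins) + 1L]] <- list(node = next_node, pend = 0)
      k <- k - 1L
    }
    if (is.finite(t) && k >= 1L)
      for (j in seq_len(k)) lins[[j]]$pend <- lins[[j]]$pend + (t - s)
    lins
  }

  ord <- nw_topo_order(nw)
  open <- list()   # per edge row (as character index): lineage list
  for (v in ord) {
    ine <- which(nw$edge[, 2] == v)
    oute <- which(nw$edge[, 1] == v)
    lab <- unname(nw$label[as.character(v)])
    lins <- list()
    if (length(oute) == 0L) {             # leaf: fresh sampled lineages
      k <- nsamp[[lab]]
      for (j in seq_len(k)) {
        tip_i <- tip_i + 1L
        tip_lab[tip_i] <- allele_names(lab, k)[j]
        lins[[j]] <- list(node = tip_i, pend = 0)
      }
    } else {
      for (e in oute) {
        lins <- c(lins, open[[as.character(e)]])
        open[[as.character(e)]] <- NULL
      }
    }
    if (length(ine) == 0L) {              # root: coalesce the rest
      lins <- run_branch(lins, Inf)
      root_node <- lins[[1]]$node
    } else if (length(ine) == 1L) {
      open[[as.character(ine)]] <- run_branch(lins, nw$len[ine])
    } else {                              # reticulation: route lineages
      g1 <- nw$gamma[ine[1]]
      take1 <- stats::runif(length(lins)) < g1
      open[[as.character(ine[1])]] <-
        run_branch(lins[take1], nw$len[ine[1]])
      open[[as.character(ine[2])]] <-
        run_branch(lins[!take1], nw$len[ine[2]])
    }
  }

  if (ntips == 1L) {
    # single-lineage degenerate case: a one-tip tree
    return(structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = tip_lab,
                          edge.length = 0, Nnode = 1L), class = "phylo"))
  }
  # renumber internal nodes to ape convention: root = ntips+1, then others
  ints <- sort(unique(edge_parent))
  remap <- integer(max(ints))
  remap[root_node] <- ntips + 1L
  rest <- setdiff(ints, root_node)
  remap[rest] <- ntips + 1L + seq_along(rest)
  child <- ifelse(edge_child > ntips, remap[pmax(edge_child, 1L)], edge_child)
  parent <- remap[edge_parent]
  phy <- structure(list(edge = cbind(parent, child), tip.label = tip_lab,
                        edge.length = edge_len, Nnode = ntips - 1L),
                   class = "phylo")
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate gene trees for many loci
#'
#' @param net a [PhyloNetwork-class] object.
#' @param config a [simConfig()] list (`loci`, `samplesPerSpecies`).
#' @return a `multiPhylo` list of rooted gene trees.
#' @export
simulateGeneTrees <- function(net, config = simConfig()) {
  nw <- as_nw(net)
  out <- vector("list", config$loci)
  for (i in seq_len(config$loci))
    out[[i]] <- sim_gene_tree_nw(nw, config$samplesPerSpecies)
  class(out) <- "multiPhylo"
  out
}

#' Simulate a sequence alignment along a gene tree
#'
#' Sites evolve i.i.d. under Jukes-Cantor (default) or GTR; the expected
#' number of substitutions per site on a branch is `theta / 2` times its
#' length in coalescent units.
#'
#' @param geneTree a `phylo` with branch lengths in coalescent units.
#' @param config a [simConfig()] list (`theta`, `seqLength`, `model`,
#'   `Q`, `bf`).
#' @return a `phyDat` alignment (one sequence per tip).
#' @export
simulateAlignment <- function(geneTree, config = simConfig()) {
  stopifnot(inherits(geneTree, "phylo"), !is.null(geneTree$edge.length))
  tr <- geneTree
  tr$edge.length <- tr$edge.length * config$theta / 2
  if (config$model == "GTR")
    phangorn::simSeq(tr, l = config$seqLength, Q = config$Q, bf = config$bf)
  else
    phangorn::simSeq(tr, l = config$seqLength)
}
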