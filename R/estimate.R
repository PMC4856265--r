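# Gene-tree re-estimation from simulated alignments (bootstrap + NJ or
# ML), and rooted Robinson-Foulds distances.

# JC69 distance matrix from a character matrix (rows = taxa); saturated
# or undefined distances are capped at a large finite value
jc_dist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- mean(mat[i, ] != mat[j, ])
      dd <- if (p >= 0.749) 5 else -3 / 4 * log(1 - 4 * p / 3)
      d[i, j] <- d[j, i] <- dd
    }
  }
  stats::as.dist(d)
}

estimate_one <- function(mat, outgroup, engine) {
  if (engine == "nj") {
    tr <- ape::nj(jc_dist(mat))
  } else {
    pd <- phangorn::phyDat(mat)
    fit <- phangorn::pml(ape::nj(jc_dist(mat)), data = pd)
    fit <- phangorn::optim.pml(fit, optNni = TRUE,
                               control = phangorn::pml.control(trace = 0))
    tr <- fit$tree
  }
  tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  tr$edge.length <- NULL
  tr
}

#' Estimate bootstrap gene trees from alignments
#'
#' For each locus alignment, draws `bootstrapReps` site-resampled
#' replicates, estimates a tree from each (neighbor joining on
#' Jukes-Cantor distances by default, or maximum likelihood via
#' \pkg{phangorn} with `engine = "ml"`), and roots it at the designated
#' outgroup. All replicate topologies are retained (no filtering); the
#' per-locus multisets are the bootstrap gene-tree data consumed by
#' [makeGeneTreeData()].
#'
#' @param alignments list of `phyDat` alignments (one per locus).
#' @param outgroup tip label used to root the estimates.
#' @param config a [simConfig()] list (`bootstrapReps`).
#' @param engine `"nj"` (fast, default) or `"ml"`.
#' @return list (per locus) of lists of rooted `phylo` topologies.
#' @export
estimateGeneTrees <- function(alignments, outgroup,
                              config = simConfig(), engine = c("nj", "ml")) {
  engine <- match.arg(engine)
  stopifnot(length(alignments) >= 1L)
  out <- vector("list", length(alignments))
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    mat <- as.character(aln)
    if (!(outgroup %in% rownames(mat)))
      stop(sprintf("locus %d: outgroup '%s' absent from alignment", i, outgroup))
    reps <- vector("list", config$bootstrapReps)
    err <- NULL
    for (b in seq_len(config$bootstrapReps)) {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      reps[[b]] <- tryCatch(estimate_one(mat[, cols, drop = FALSE],
                                         outgroup, engine),
                            error = function(e) {
                              err <<- conditionMessage(e)
                              NULL
                            })
    }
    if (any(vapply(reps, is.null, TRUE)))
      stop(sprintf("tree estimation failed for locus %d: %s", i, err))
    out[[i]] <- reps
  }
  out
}

# nontrivial clades (leaf sets below internal non-root nodes) of a
# rooted tree, as sorted strings
clades_of <- function(phy) {
  nt <- length(phy$tip.label)
  chl <- split(phy$edge[, 2], phy$edge[, 1])
  root <- setdiff(unique(phy$edge[, 1]), phy$edge[, 2])
  out <- character(0)
  rec <- function(v) {
    if (v <= nt) return(phy$tip.label[v])
    tips <- sort(unlist(lapply(chl[[as.character(v)]], rec)))
    if (v != root) out <<- c(out, paste(tips, collapse = "\r"))
    tips
  }
  rec(root)
  out
}

#' Rooted Robinson-Foulds distance, normalized
#'
#' The symmetric difference of the nontrivial clades (clusters induced by
#' internal edges, excluding the root and the leaves) of two rooted
#' topologies on the same leaf set, divided by the total number of clades
#' compared. 0 for identical topologies; 1 when no nontrivial clade is
#' shared.
#'
#' @param t1,t2 rooted `phylo` objects or Newick strings.
#' @return a number in `[0, 1]`.
#' @export
rfDistance <- function(t1, t2) {
  t1 <- as_phylo_tree(t1); t2 <- as_phylo_tree(t2)
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("rfDistance requires identical leaf sets")
  c1 <- clades_of(t1); c2 <- clades_of(t2)
  if (!length(c1) && !length(c2)) return(0)
  (sum(!(c1 %in% c2)) + sum(!(c2 %in% c1))) / (length(c1) + length(c2))
}
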