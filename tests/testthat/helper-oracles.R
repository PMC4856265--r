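# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: isomorphism is decided by exhaustive node
# bijection, and the species-tree gene-tree probability is computed from
# the classical coalescent-history sum (histories enumerated explicitly,
# orderings counted with the forest hook-length formula), not by the
# package's configuration dynamic program.

nwx <- function(net) netcoal:::as_nw(net)

# exhaustive leaf-label-preserving DAG isomorphism
iso_networks <- function(a, b) {
  a <- nwx(a); b <- nwx(b)
  ia <- netcoal:::nw_ids(a); ib <- netcoal:::nw_ids(b)
  if (length(ia) != length(ib) || nrow(a$edge) != nrow(b$edge)) return(FALSE)
  dega <- netcoal:::nw_degrees(a); degb <- netcoal:::nw_degrees(b)
  la <- a$label[as.character(ia)]; lb <- b$label[as.character(ib)]
  k <- length(ia)
  edgeb <- paste(b$edge[, 1], b$edge[, 2])
  # candidate images per node of a
  cand <- lapply(seq_len(k), function(i) {
    ok <- dega$indeg[i] == degb$indeg & dega$outdeg[i] == degb$outdeg
    if (!is.na(la[i])) ok <- ok & !is.na(lb) & lb == la[i]
    else ok <- ok & is.na(lb)
    which(ok)
  })
  assign_next <- function(map, used) {
    i <- length(map) + 1L
    if (i > k) {
      ea <- paste(ib[map[match(a$edge[, 1], ia)]], ib[map[match(a$edge[, 2], ia)]])
      return(setequal(ea, edgeb) && length(ea) == length(edgeb))
    }
    for (j in cand[[i]]) {
      if (used[j]) next
      if (assign_next(c(map, j), replace(used, j, TRUE))) return(TRUE)
    }
    FALSE
  }
  assign_next(integer(0), rep(FALSE, k))
}

# linear extensions of the gene-tree ancestry order restricted to a node
# set, by the forest hook-length formula: n! / prod(subtree sizes). The
# covering forest links each node to its nearest ancestor within the set.
forest_orderings <- function(nodes, parent_full) {
  if (!length(nodes)) return(1)
  setpar <- vapply(nodes, function(v) {
    p <- parent_full[v]
    while (p != 0L && !(p %in% nodes)) p <- parent_full[p]
    p
  }, 0L)
  size <- function(v) 1 + sum(vapply(nodes[setpar == v], size, 0))
  factorial(length(nodes)) / prod(vapply(nodes, size, 0))
}

# P(gene tree topology | species TREE) via the coalescent-history sum:
# every assignment of gene-tree internal nodes to species-tree branches
# (respecting the MRCA lower bound and parent-above-child), with
# per-branch w/d ordering weights and Tavare transition factors.
msc_tree_prob <- function(net, gene) {
  nw <- nwx(net)
  stopifnot(length(netcoal:::nw_retic_nodes(nw)) == 0L)
  gt <- netcoal:::encode_gene_tree(gene)
  L <- length(gene$tip.label)
  gnodes <- seq_len(2L * L - 1L)
  ginternal <- gnodes[-seq_len(L)]
  gpar <- gt$parent
  # species below each gene node
  gdesc <- lapply(gnodes, function(v) {
    below <- v
    repeat {
      nxt <- unique(c(below, gnodes[gpar %in% below]))
      if (length(nxt) == length(below)) break
      below <- nxt
    }
    gt$species[below[below <= L]]
  })
  # species-tree structure: edges + virtual root branch (id 0)
  ids <- netcoal:::nw_ids(nw)
  E <- nrow(nw$edge)
  desc_sp <- function(v) {
    ch <- netcoal:::nw_children(nw, v)
    if (!length(ch)) return(unname(nw$label[as.character(v)]))
    unlist(lapply(ch, desc_sp))
  }
  branch_sp <- lapply(seq_len(E), function(i) desc_sp(nw$edge[i, 2]))
  # branch b is ancestral-or-equal to branch a (0 = root branch, above all)
  anc <- function(b, a) {
    if (b == 0L) return(TRUE)
    if (a == 0L) return(FALSE)
    all(branch_sp[[a]] %in% branch_sp[[b]])
  }
  # minimal branch for gene node: smallest branch containing its species
  minb <- vapply(ginternal, function(v) {
    okb <- which(vapply(seq_len(E), function(i)
      all(gdesc[[v]] %in% branch_sp[[i]]), TRUE))
    if (!length(okb)) return(0L)
    sizes <- vapply(okb, function(i) length(branch_sp[[i]]), 0)
    okb[which.min(sizes)]
  }, 0L)
  # entering lineage counts: leaves enter at their species' terminal branch
  enter0 <- vapply(seq_len(E), function(i) {
    v <- nw$edge[i, 2]
    lab <- nw$label[as.character(v)]
    if (is.na(lab)) 0L else sum(gt$species == lab)
  }, 0L)
  children_of <- lapply(seq_len(E), function(i)
    which(nw$edge[, 1] == nw$edge[i, 2]))
  root_children <- which(nw$edge[, 1] == nw$root)

  choices <- lapply(ginternal, function(v)
    c(0L, which(vapply(seq_len(E), function(i) anc(i, minb[match(v, ginternal)]),
                       TRUE))))
  total <- 0
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(grid))) {
    h <- as.integer(grid[r, ])
    names(h) <- as.character(ginternal)
    # parent-above-child consistency
    ok <- TRUE
    for (v in ginternal) {
      p <- gpar[v]
      if (p != 0L && !anc(h[[as.character(p)]], h[[as.character(v)]])) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    # lineages entering each branch, bottom-up
    into <- enter0
    coal_in <- lapply(seq_len(E), function(i) ginternal[h == i])
    pr <- 1
    vcount <- integer(E)
    for (i in order(vapply(seq_len(E), function(i) length(branch_sp[[i]]), 0))) {
      u <- into[i] + sum(vapply(children_of[[i]], function(j) vcount[j], 0L))
      nc <- length(coal_in[[i]])
      v <- u - nc
      if (u == 0L && nc == 0L) { vcount[i] <- 0L; next }
      if (v < 1L) { pr <- 0; break }
      d <- prod(vapply(seq_len(nc), function(j) choose(u - j + 1L, 2L), 0))
      w <- forest_orderings(coal_in[[i]], gpar)
      pr <- pr * w / d * coalescenceProb(u, v, nw$len[i])
      vcount[i] <- v
      if (pr == 0) break
    }
    if (pr == 0) next
    # root branch: everything coalesces
    u <- sum(vapply(root_children, function(j) vcount[j], 0L))
    rootset <- ginternal[h == 0L]
    nc <- length(rootset)
    if (u - nc != 1L) next
    d <- prod(vapply(seq_len(nc), function(j) choose(u - j + 1L, 2L), 0))
    w <- forest_orderings(rootset, gpar)
    pr <- pr * w / d
    total <- total + pr
  }
  total
}

# random lengths and inheritance probabilities on an enumerated topology
randomize_nw <- function(nw, rate = 1) {
  nw <- nwx(nw)
  nw$len <- stats::rexp(length(nw$len), rate)
  for (v in netcoal:::nw_retic_nodes(nw)) {
    ein <- which(nw$edge[, 2] == v)
    g <- stats::runif(1)
    nw$gamma[ein] <- c(g, 1 - g)
  }
  nw
}

# exact equality of two internal network representations (stable ids)
nw_identical <- function(a, b, tol = 1e-9) {
  ka <- paste(a$edge[, 1], a$edge[, 2])
  kb <- paste(b$edge[, 1], b$edge[, 2])
  if (!setequal(ka, kb) || length(ka) != length(kb)) return(FALSE)
  m <- match(ka, kb)
  ga <- ifelse(is.na(a$gamma), -1, a$gamma)
  gb <- ifelse(is.na(b$gamma[m]), -1, b$gamma[m])
  all(abs(a$len - b$len[m]) < tol) && all(abs(ga - gb) < tol) &&
    a$root == b$root
}

# all rooted binary gene-tree topologies on a label set, as phylo objects
all_tree_phylos <- function(labels) {
  lapply(netcoal:::enumerate_trees_nw(labels), function(tr)
    ape::read.tree(text = netcoal:::write_enewick_nw(tr, lengths = FALSE)))
}
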