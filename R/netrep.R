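# Internal light-weight network representation used by the MCMC hot path.
#
# A `nw` is a plain list:
#   edge  : integer matrix, E x 2, columns (tail, head); ids are arbitrary
#           positive integers that stay stable across proposal moves
#   len   : numeric length E, branch lengths in coalescent units
#   gamma : numeric length E, inheritance probability of the edge when its
#           head is a reticulation node, NA otherwise; the two in-edges of a
#           reticulation node sum to 1
#   label : named character, names are leaf node ids (as character)
#   root  : integer id of the root
#
# The exported S4 class PhyloNetwork mirrors these fields; conversion is a
# reslotting, no copying logic.

new_nw <- function(edge, len, gamma, label, root) {
  storage.mode(edge) <- "integer"
  list(edge = edge, len = as.numeric(len), gamma = as.numeric(gamma),
       label = label, root = as.integer(root))
}

nw_ids <- function(nw) sort(unique(as.integer(nw$edge)))

# smallest positive integer not currently used as a node id
nw_new_id <- function(nw, k = 1L) {
  used <- nw_ids(nw)
  cand <- setdiff(seq_len(length(used) + k), used)
  cand[seq_len(k)]
}

nw_children <- function(nw, v) nw$edge[nw$edge[, 1] == v, 2]
nw_parents <- function(nw, v) nw$edge[nw$edge[, 2] == v, 1]

# in/out degrees aligned with ids
nw_degrees <- function(nw) {
  ids <- nw_ids(nw)
  list(ids = ids,
       indeg = tabulate(match(nw$edge[, 2], ids), length(ids)),
       outdeg = tabulate(match(nw$edge[, 1], ids), length(ids)))
}

nw_ntaxa <- function(nw) length(nw$label)

nw_nretic <- function(nw) {
  h <- nw$edge[, 2]
  sum(tabulate(match(h, unique(h)), length(unique(h))) == 2L)
}

# reticulation node ids (indeg 2)
nw_retic_nodes <- function(nw) {
  h <- nw$edge[, 2]
  u <- unique(h)
  u[tabulate(match(h, u), length(u)) == 2L]
}

# edge row indices whose head is a reticulation node
nw_retic_edges <- function(nw) which(nw$edge[, 2] %in% nw_retic_nodes(nw))

nw_leaves <- function(nw) as.integer(names(nw$label))

# Kahn topological order of node ids, leaves first (children before parents).
# Returns NULL when the graph has a directed cycle.
nw_topo_order <- function(nw) {
  ids <- nw_ids(nw)
  k <- length(ids)
  tl <- match(nw$edge[, 1], ids)
  hd <- match(nw$edge[, 2], ids)
  outdeg <- tabulate(tl, k)
  remaining <- outdeg
  order <- integer(0)
  queue <- which(remaining == 0L)
  seen <- rep(FALSE, k)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (seen[v]) next
    seen[v] <- TRUE
    order <- c(order, v)
    # processing v removes its in-edges: decrement the out-degree of its parents
    for (p in tl[hd == v]) {
      remaining[p] <- remaining[p] - 1L
      if (remaining[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(order) < k) return(NULL)
  ids[order]
}

# Structural validation; returns a data.frame(kind, detail), empty when valid.
nw_validate <- function(nw) {
  bad <- list()
  note <- function(kind, detail) bad[[length(bad) + 1L]] <<- data.frame(
    kind = kind, detail = detail, stringsAsFactors = FALSE)

  if (!is.matrix(nw$edge) || ncol(nw$edge) != 2L || nrow(nw$edge) < 1L) {
    note("degree-violation", "edge matrix malformed or empty")
    return(do.call(rbind, bad))
  }
  ids <- nw_ids(nw)
  k <- length(ids)
  tl <- match(nw$edge[, 1], ids)
  hd <- match(nw$edge[, 2], ids)
  indeg <- tabulate(hd, k)
  outdeg <- tabulate(tl, k)

  dup <- duplicated(paste(nw$edge[, 1], nw$edge[, 2]))
  if (any(dup))
    for (i in which(dup))
      note("parallel-edge", sprintf("duplicated edge (%d,%d)",
                                    nw$edge[i, 1], nw$edge[i, 2]))

  roots <- ids[indeg == 0L]
  if (length(roots) > 1L)
    note("multiple-roots", sprintf("in-degree-0 nodes: %s",
                                   paste(roots, collapse = ", ")))
  if (length(roots) == 0L)
    note("cycle", "no node of in-degree 0")
  if (length(roots) == 1L && !identical(as.integer(roots), nw$root))
    note("degree-violation", sprintf("root slot %d is not the in-degree-0 node %d",
                                     nw$root, roots))

  leaf_ids <- suppressWarnings(as.integer(names(nw$label)))
  for (i in seq_len(k)) {
    v <- ids[i]
    din <- indeg[i]; dout <- outdeg[i]
    ok <- (din == 0L && dout == 2L) ||   # root
          (din == 1L && dout == 0L) ||   # leaf
          (din == 1L && dout == 2L) ||   # internal tree node
          (din == 2L && dout == 1L)      # reticulation node
    if (!ok && !(din == 0L && length(roots) > 1L))
      note("degree-violation", sprintf("node %d has in-degree %d, out-degree %d",
                                       v, din, dout))
    if (din == 0L && dout == 2L && length(roots) > 1L && v != nw$root)
      note("multiple-roots", sprintf("extra root-like node %d", v))
    if (dout == 0L && !(v %in% leaf_ids))
      note("degree-violation", sprintf("unlabeled sink node %d", v))
    if (dout > 0L && v %in% leaf_ids)
      note("degree-violation", sprintf("labeled node %d is not a leaf", v))
  }
  if (anyDuplicated(nw$label))
    note("degree-violation", sprintf("duplicate leaf label '%s'",
                                     nw$label[duplicated(nw$label)][1]))

  if (is.null(nw_topo_order(nw)))
    note("cycle", "directed cycle present")

  if (any(is.na(nw$len)) || any(nw$len < 0))
    note("negative-length", sprintf("branch length negative or missing on edge row %d",
                                    which(is.na(nw$len) | nw$len < 0)[1]))

  # gamma bookkeeping: present exactly on reticulation in-edges, pairs sum to 1
  re <- nw_retic_edges(nw)
  if (length(re)) {
    g <- nw$gamma[re]
    if (any(is.na(g))) {
      note("degree-violation", "missing inheritance probability on a reticulation edge")
    } else {
      for (v in nw_retic_nodes(nw)) {
        ein <- which(nw$edge[, 2] == v)
        if (length(ein) == 2L && abs(sum(nw$gamma[ein]) - 1) > 1e-9)
          note("degree-violation",
               sprintf("inheritance probabilities at node %d sum to %g", v,
                       sum(nw$gamma[ein])))
      }
    }
  }
  if (any(!is.na(nw$gamma[setdiff(seq_len(nrow(nw$edge)), re)])))
    note("degree-violation", "inheritance probability on a non-reticulation edge")

  if (length(bad)) do.call(rbind, bad)
  else data.frame(kind = character(0), detail = character(0),
                  stringsAsFactors = FALSE)
}

nw_is_valid <- function(nw) nrow(nw_validate(nw)) == 0L

# split edge row i at distance h from its tail; returns list(nw, node = new id)
nw_split_edge <- function(nw, i, h, id = NULL) {
  if (is.null(id)) id <- nw_new_id(nw)
  a <- nw$edge[i, 1]; b <- nw$edge[i, 2]
  lo_gamma <- nw$gamma[i]          # the lower half keeps the head, hence gamma
  lo_len <- nw$len[i] - h
  nw$edge[i, ] <- c(a, id)
  nw$len[i] <- h
  nw$gamma[i] <- NA_real_
  nw$edge <- rbind(nw$edge, c(id, b))
  nw$len <- c(nw$len, lo_len)
  nw$gamma <- c(nw$gamma, lo_gamma)
  list(nw = nw, node = id)
}

# suppress a degree-(1,1) node v: merge its in-edge and out-edge, lengths summed
nw_suppress <- function(nw, v) {
  ein <- which(nw$edge[, 2] == v)
  eout <- which(nw$edge[, 1] == v)
  stopifnot(length(ein) == 1L, length(eout) == 1L)
  a <- nw$edge[ein, 1]; b <- nw$edge[eout, 2]
  newlen <- nw$len[ein] + nw$len[eout]
  newgam <- nw$gamma[eout]         # head of merged edge is b
  keep <- setdiff(seq_len(nrow(nw$edge)), c(ein, eout))
  nw$edge <- rbind(nw$edge[keep, , drop = FALSE], c(a, b))
  nw$len <- c(nw$len[keep], newlen)
  nw$gamma <- c(nw$gamma[keep], newgam)
  nw
}

edge_row <- function(nw, tail, head) {
  which(nw$edge[, 1] == tail & nw$edge[, 2] == head)
}
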