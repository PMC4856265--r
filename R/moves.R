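# The seven proposal moves of the reversible-jump sampler, the
# hierarchical move-selection scheme, and per-move log Hastings ratios.
#
# Moves return the raw candidate even when it violates the network
# definition (cycle, parallel edge, extra root): validity is the prior's
# job, and invalid candidates are always rejected there. Each proposal
# also returns the forced-choice list that deterministically reproduces
# its exact reverse, which the test harness uses to verify that
# log-Hastings (+ log-Jacobian) terms negate across a forward/reverse
# pair.
#
# Continuous perturbations are symmetric uniform windows with reflection
# (branch lengths at 0, inheritance probabilities at 0 and 1), so moves
# 1-2 are Hastings-neutral. Add-Reticulation draws the new edge length
# from Exponential(addLengthRate) and the new inheritance probability
# uniformly; with attachment heights uniform along the chosen edges the
# dimension-matching map is identity-like and its Jacobian is 1.

MOVE_KINDS <- c("changeLength", "changeInheritance", "moveTail", "moveHead",
                "flipReticulation", "addReticulation", "deleteReticulation")

#' Move configuration
#'
#' Hierarchical move selection: with probability `kappa` a
#' dimension-changing move (Add-Reticulation with probability `kappa1`,
#' else Delete-Reticulation); with probability `1 - kappa` a
#' non-dimension-changing move, which is non-topological with probability
#' `omega` (Change-Length with probability `omega1`, else
#' Change-Inheritance) and topological otherwise (Move-Tail, Move-Head,
#' Flip-Reticulation with probabilities `xi[1:3]`, summing to 1). On a
#' tree, the moves requiring a reticulation have probability 0:
#' Add-Reticulation absorbs Delete's mass, Change-Length absorbs
#' Change-Inheritance's, and Move-Tail absorbs the whole topological
#' branch.
#'
#' @param kappa probability of a dimension-changing move.
#' @param kappa1 P(Add-Reticulation | dimension-changing).
#' @param omega P(non-topology move | non-dimension-changing).
#' @param omega1 P(Change-Length | non-topology).
#' @param xi length-3 probabilities of Move-Tail / Move-Head /
#'   Flip-Reticulation; must sum to 1.
#' @param lengthWindow half-width of the branch-length perturbation
#'   window (coalescent units).
#' @param gammaWindow half-width of the inheritance-probability window
#'   (at most 0.5 so a draw reflects at most once).
#' @param maxReticulations hard cap on the reticulation count; `NULL`
#'   means (number of taxa - 1), resolved at run time.
#' @param addLengthRate rate of the Exponential proposal for the new
#'   reticulation-edge length (defaults to the branch-length prior rate).
#' @return a validated list of class `move_config`.
#' @export
moveConfig <- function(kappa = 0.2, kappa1 = 0.5, omega = 0.5, omega1 = 0.5,
                       xi = c(1, 1, 1) / 3, lengthWindow = 0.5,
                       gammaWindow = 0.1, maxReticulations = NULL,
                       addLengthRate = NULL) {
  stopifnot(kappa >= 0, kappa <= 1, kappa1 >= 0, kappa1 <= 1,
            omega >= 0, omega <= 1, omega1 >= 0, omega1 <= 1,
            length(xi) == 3L, all(xi >= 0), abs(sum(xi) - 1) < 1e-9,
            lengthWindow > 0, gammaWindow > 0, gammaWindow <= 0.5,
            is.null(addLengthRate) || addLengthRate > 0)
  structure(list(kappa = kappa, kappa1 = kappa1, omega = omega,
                 omega1 = omega1, xi = xi, lengthWindow = lengthWindow,
                 gammaWindow = gammaWindow,
                 maxReticulations = maxReticulations,
                 addLengthRate = addLengthRate),
            class = "move_config")
}

# per-state selection probabilities of the seven moves (queryable; these
# enter the Hastings ratio of the dimension-changing pair)
move_probs <- function(nw, cfg) {
  # valid binary networks satisfy E = 2n - 2 + 3m, so the reticulation
  # count is affine in the edge count (moves keep candidates in this
  # family or hand them to the prior, which rejects them regardless)
  hasR <- nrow(nw$edge) > 2L * length(nw$label) - 2L
  c(changeLength = (1 - cfg$kappa) * cfg$omega * (if (hasR) cfg$omega1 else 1),
    changeInheritance = (1 - cfg$kappa) * cfg$omega *
      (if (hasR) 1 - cfg$omega1 else 0),
    moveTail = (1 - cfg$kappa) * (1 - cfg$omega) * (if (hasR) cfg$xi[1] else 1),
    moveHead = (1 - cfg$kappa) * (1 - cfg$omega) * (if (hasR) cfg$xi[2] else 0),
    flipReticulation = (1 - cfg$kappa) * (1 - cfg$omega) *
      (if (hasR) cfg$xi[3] else 0),
    addReticulation = cfg$kappa * (if (hasR) cfg$kappa1 else 1),
    deleteReticulation = cfg$kappa * (if (hasR) 1 - cfg$kappa1 else 0))
}

select_move_nw <- function(nw, cfg) {
  p <- move_probs(nw, cfg)
  r <- stats::runif(1) * sum(p)
  MOVE_KINDS[which(cumsum(p) >= r)[1]]
}

#' Query per-state move-selection probabilities
#'
#' @param net a [PhyloNetwork-class] object (current state).
#' @param config a [moveConfig()] list.
#' @return named numeric vector over the seven move kinds, summing to 1.
#' @export
moveProbabilities <- function(net, config = moveConfig()) {
  move_probs(as_nw(net), config)
}

#' Select a proposal move
#'
#' Draws one of the seven move kinds according to the hierarchical scheme
#' described in [moveConfig()].
#'
#' @inheritParams moveProbabilities
#' @return a move-kind string.
#' @export
selectMove <- function(net, config = moveConfig()) {
  select_move_nw(as_nw(net), config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

skip_result <- function(kind) {
  list(ok = FALSE, kind = kind, nw = NULL, logH = NA_real_, logJ = NA_real_)
}

# unsorted degree tabulation (cheaper than nw_degrees on the hot path)
nw_degs_fast <- function(nw) {
  ids <- unique(as.integer(nw$edge))
  list(ids = ids,
       indeg = tabulate(match(nw$edge[, 2], ids), length(ids)),
       outdeg = tabulate(match(nw$edge[, 1], ids), length(ids)))
}

# edges whose tail is an internal (non-root) tree node
tail_eligible <- function(nw) {
  deg <- nw_degs_fast(nw)
  treeint <- deg$ids[deg$indeg == 1L & deg$outdeg == 2L]
  which(nw$edge[, 1] %in% treeint)
}

delete_eligible <- function(nw) {
  re <- nw_retic_edges(nw)
  deg <- nw_degs_fast(nw)
  treeint <- deg$ids[deg$indeg == 1L & deg$outdeg == 2L]
  re[nw$edge[re, 1] %in% treeint]
}


# resolve an edge row from a (tail, head) pair; intermediate graphs may
# carry parallel edges, so an expected length disambiguates
resolve_edge <- function(nw, pair, len = NULL) {
  rows <- edge_row(nw, pair[1], pair[2])
  if (length(rows) > 1L && !is.null(len))
    rows <- rows[which.min(abs(nw$len[rows] - len))]
  rows[1]
}

fold01 <- function(x) {
  repeat {
    if (x < 0) x <- -x
    else if (x > 1) x <- 2 - x
    else return(x)
  }
}

propose_change_length <- function(nw, cfg, choices = NULL) {
  E <- nrow(nw$edge)
  i <- if (!is.null(choices)) edge_row(nw, choices$edge[1], choices$edge[2])
       else sample.int(E, 1L)
  u <- choices$delta %||% stats::runif(1, -cfg$lengthWindow, cfg$lengthWindow)
  old <- nw$len[i]
  nw$len[i] <- abs(old + u)
  list(ok = TRUE, kind = "changeLength", nw = nw, logH = 0, logJ = 0,
       reverse = list(edge = nw$edge[i, ], delta = old - nw$len[i]))
}

propose_change_inheritance <- function(nw, cfg, choices = NULL) {
  nodes <- nw_retic_nodes(nw)
  if (!length(nodes)) stop("Change-Inheritance requires a reticulation node")
  v <- choices$node %||% nodes[sample.int(length(nodes), 1L)]
  ein <- which(nw$edge[, 2] == v)
  u <- choices$delta %||% stats::runif(1, -cfg$gammaWindow, cfg$gammaWindow)
  old <- nw$gamma[ein[1]]
  g <- fold01(old + u)
  nw$gamma[ein[1]] <- g
  nw$gamma[ein[2]] <- 1 - g
  list(ok = TRUE, kind = "changeInheritance", nw = nw, logH = 0, logJ = 0,
       reverse = list(node = v, delta = old - g))
}

propose_move_tail <- function(nw, cfg, choices = NULL) {
  elig <- tail_eligible(nw)
  Fn <- length(elig)
  if (!Fn) return(skip_result("moveTail"))
  ei <- if (!is.null(choices)) edge_row(nw, choices$edge[1], choices$edge[2])
        else elig[sample.int(Fn, 1L)]
  x <- nw$edge[ei, 1]; v <- nw$edge[ei, 2]
  px <- which(nw$edge[, 2] == x)
  outx <- which(nw$edge[, 1] == x)
  xc <- setdiff(outx, ei)
  p <- nw$edge[px, 1]; cc <- nw$edge[xc, 2]
  Lrev <- nw$len[px] + nw$len[xc]

  # suppress x on its old position: merge (p,x)+(x,cc); keep (x,v) dangling
  keep <- setdiff(seq_len(nrow(nw$edge)), c(px, xc))
  nw2 <- nw
  nw2$edge <- rbind(nw$edge[keep, , drop = FALSE], c(p, cc))
  nw2$len <- c(nw$len[keep], Lrev)
  nw2$gamma <- c(nw$gamma[keep], nw$gamma[xc])
  mi <- edge_row(nw2, x, v)

  dests <- setdiff(seq_len(nrow(nw2$edge)), mi)
  Dn <- length(dests)
  di <- if (!is.null(choices)) resolve_edge(nw2, choices$dest, choices$destLen)
        else dests[sample.int(Dn, 1L)]
  dlen <- nw2$len[di]
  h <- choices$h %||% stats::runif(1, 0, dlen)
  cand <- nw_split_edge(nw2, di, h, id = x)$nw

  Fr <- length(tail_eligible(cand))
  # reverse intermediate has the same edge count as the forward one
  Dr <- nrow(nw2$edge) - 1L
  logH <- (log(Fn) + log(Dn) + log(dlen)) - (log(Fr) + log(Dr) + log(Lrev))
  list(ok = TRUE, kind = "moveTail", nw = cand, logH = logH, logJ = 0,
       reverse = list(edge = c(x, v), dest = c(p, cc), destLen = Lrev,
                      h = nw$len[px]))
}

propose_move_head <- function(nw, cfg, choices = NULL) {
  elig <- nw_retic_edges(nw)
  Fn <- length(elig)
  if (!Fn) return(skip_result("moveHead"))
  ei <- if (!is.null(choices)) edge_row(nw, choices$edge[1], choices$edge[2])
        else elig[sample.int(Fn, 1L)]
  u <- nw$edge[ei, 1]; r <- nw$edge[ei, 2]
  wr <- setdiff(which(nw$edge[, 2] == r), ei)
  rz <- which(nw$edge[, 1] == r)
  w <- nw$edge[wr, 1]; z <- nw$edge[rz, 2]
  g_e <- nw$gamma[ei]
  Lrev <- nw$len[wr] + nw$len[rz]

  keep <- setdiff(seq_len(nrow(nw$edge)), c(wr, rz))
  nw2 <- nw
  nw2$edge <- rbind(nw$edge[keep, , drop = FALSE], c(w, z))
  nw2$len <- c(nw$len[keep], Lrev)
  nw2$gamma <- c(nw$gamma[keep], nw$gamma[rz])
  mi <- edge_row(nw2, u, r)
  nw2$gamma[mi] <- NA_real_          # r is not a reticulation while dangling

  dests <- setdiff(seq_len(nrow(nw2$edge)), mi)
  Dn <- length(dests)
  di <- if (!is.null(choices)) resolve_edge(nw2, choices$dest, choices$destLen)
        else dests[sample.int(Dn, 1L)]
  dlen <- nw2$len[di]
  h <- choices$h %||% stats::runif(1, 0, dlen)
  cand <- nw_split_edge(nw2, di, h, id = r)$nw
  # r is a reticulation again: gamma of the moved edge is preserved
  cand$gamma[edge_row(cand, u, r)] <- g_e
  upper <- which(cand$edge[, 2] == r & cand$edge[, 1] != u)
  cand$gamma[upper] <- 1 - g_e

  Fr <- length(nw_retic_edges(cand))
  Dr <- nrow(nw2$edge) - 1L
  logH <- (log(Fn) + log(Dn) + log(dlen)) - (log(Fr) + log(Dr) + log(Lrev))
  list(ok = TRUE, kind = "moveHead", nw = cand, logH = logH, logJ = 0,
       reverse = list(edge = c(u, r), dest = c(w, z), destLen = Lrev,
                      h = nw$len[wr]))
}

# reticulation edges whose tail is an internal tree node (flip-eligible)
flip_eligible <- function(nw) {
  re <- nw_retic_edges(nw)
  deg <- nw_degs_fast(nw)
  treeint <- deg$ids[deg$indeg == 1L & deg$outdeg == 2L]
  re[nw$edge[re, 1] %in% treeint]
}

propose_flip_reticulation <- function(nw, cfg, choices = NULL) {
  elig <- flip_eligible(nw)
  Fn <- length(elig)
  if (!Fn) return(skip_result("flipReticulation"))
  ei <- if (!is.null(choices)) edge_row(nw, choices$edge[1], choices$edge[2])
        else elig[sample.int(Fn, 1L)]
  u <- nw$edge[ei, 1]; r <- nw$edge[ei, 2]
  g_e <- nw$gamma[ei]
  wr <- setdiff(which(nw$edge[, 2] == r), ei)
  pu <- which(nw$edge[, 2] == u)
  gnew <- choices$gamma %||% stats::runif(1)

  cand <- nw
  cand$edge[ei, ] <- c(r, u)
  cand$gamma[ei] <- gnew           # in-edge of the new reticulation u
  cand$gamma[wr] <- NA_real_       # r is now a tree node
  cand$gamma[pu] <- 1 - gnew
  Fr <- length(flip_eligible(cand))
  logH <- log(Fn) - log(Fr)        # uniform gamma densities cancel
  list(ok = TRUE, kind = "flipReticulation", nw = cand, logH = logH, logJ = 0,
       reverse = list(edge = c(r, u), gamma = g_e))
}

propose_add_reticulation <- function(nw, cfg, choices = NULL) {
  m <- length(nw_retic_nodes(nw))
  cap <- cfg$maxReticulations %||% (nw_ntaxa(nw) - 1L)
  if (m >= cap) return(skip_result("addReticulation"))
  E <- nrow(nw$edge)
  i1 <- if (!is.null(choices)) edge_row(nw, choices$edge1[1], choices$edge1[2])
        else sample.int(E, 1L)
  i2 <- if (!is.null(choices)) edge_row(nw, choices$edge2[1], choices$edge2[2])
        else sample.int(E, 1L)
  len1 <- nw$len[i1]; len2 <- nw$len[i2]
  h1 <- choices$h1 %||% stats::runif(1, 0, len1)
  h2 <- choices$h2 %||% stats::runif(1, 0, len2)
  rate <- cfg$addLengthRate %||% 1
  ell <- choices$len %||% stats::rexp(1, rate)
  gnew <- choices$gamma %||% stats::runif(1)
  ids <- nw_new_id(nw, 2L)
  s <- ids[1]; r <- ids[2]

  if (i1 != i2) {
    cand <- nw_split_edge(nw, i1, h1, id = s)$nw
    cand <- nw_split_edge(cand, i2, h2, id = r)$nw
  } else {
    # both attachment points on the same edge; always invalid downstream
    if (h1 <= h2) {
      cand <- nw_split_edge(nw, i1, h1, id = s)$nw
      low <- edge_row(cand, s, nw$edge[i1, 2])
      cand <- nw_split_edge(cand, low, h2 - h1, id = r)$nw
    } else {
      cand <- nw_split_edge(nw, i1, h2, id = r)$nw
      low <- edge_row(cand, r, nw$edge[i1, 2])
      cand <- nw_split_edge(cand, low, h1 - h2, id = s)$nw
    }
  }
  cand$edge <- rbind(cand$edge, c(s, r))
  cand$len <- c(cand$len, ell)
  cand$gamma <- c(cand$gamma, gnew)
  upper <- which(cand$edge[, 2] == r & cand$edge[, 1] != s)
  cand$gamma[upper] <- 1 - gnew

  p_add <- move_probs(nw, cfg)["addReticulation"]
  p_del <- move_probs(cand, cfg)["deleteReticulation"]
  Rrev <- length(delete_eligible(cand))
  q_fwd <- log(p_add) - 2 * log(E) - log(len1) - log(len2) +
    stats::dexp(ell, rate, log = TRUE)
  q_rev <- log(p_del) - log(Rrev)
  list(ok = TRUE, kind = "addReticulation", nw = cand,
       logH = q_rev - q_fwd, logJ = 0,
       reverse = list(edge = c(s, r)))
}

propose_delete_reticulation <- function(nw, cfg, choices = NULL) {
  elig <- delete_eligible(nw)
  Rn <- length(elig)
  if (!Rn) return(skip_result("deleteReticulation"))
  ei <- if (!is.null(choices)) edge_row(nw, choices$edge[1], choices$edge[2])
        else elig[sample.int(Rn, 1L)]
  s <- nw$edge[ei, 1]; r <- nw$edge[ei, 2]
  ps <- which(nw$edge[, 2] == s)
  sb <- setdiff(which(nw$edge[, 1] == s), ei)
  cr <- setdiff(which(nw$edge[, 2] == r), ei)
  rd <- which(nw$edge[, 1] == r)
  a <- nw$edge[ps, 1]; b <- nw$edge[sb, 2]
  cc <- nw$edge[cr, 1]; d <- nw$edge[rd, 2]
  lam1 <- nw$len[ps] + nw$len[sb]
  lam2 <- nw$len[cr] + nw$len[rd]
  ell <- nw$len[ei]
  gold <- nw$gamma[ei]

  cand <- nw
  keep <- setdiff(seq_len(nrow(cand$edge)), ei)
  cand$edge <- cand$edge[keep, , drop = FALSE]
  cand$len <- cand$len[keep]
  cand$gamma <- cand$gamma[keep]
  cand$gamma[edge_row(cand, cc, r)] <- NA_real_   # r loses reticulation status
  cand <- nw_suppress(cand, s)
  cand <- nw_suppress(cand, r)

  p_del <- move_probs(nw, cfg)["deleteReticulation"]
  p_add <- move_probs(cand, cfg)["addReticulation"]
  Er <- nrow(cand$edge)
  q_fwd <- log(p_del) - log(Rn)
  q_rev <- log(p_add) - 2 * log(Er) - log(lam1) - log(lam2) +
    stats::dexp(ell, cfg$addLengthRate %||% 1, log = TRUE)
  list(ok = TRUE, kind = "deleteReticulation", nw = cand,
       logH = q_rev - q_fwd, logJ = 0,
       reverse = list(edge1 = c(a, b), edge2 = c(cc, d), h1 = nw$len[ps],
                      h2 = nw$len[cr], len = ell, gamma = gold))
}

propose_nw <- function(nw, kind, cfg, choices = NULL) {
  switch(kind,
         changeLength = propose_change_length(nw, cfg, choices),
         changeInheritance = propose_change_inheritance(nw, cfg, choices),
         moveTail = propose_move_tail(nw, cfg, choices),
         moveHead = propose_move_head(nw, cfg, choices),
         flipReticulation = propose_flip_reticulation(nw, cfg, choices),
         addReticulation = propose_add_reticulation(nw, cfg, choices),
         deleteReticulation = propose_delete_reticulation(nw, cfg, choices),
         stop(sprintf("unknown move kind '%s'", kind)))
}

#' Propose a new state with one of the seven moves
#'
#' Applies the named move to the current network and returns the raw
#' candidate together with the log Hastings ratio and log Jacobian. The
#' candidate may violate the network definition (for example, relocations
#' can create cycles or parallel edges); such candidates receive prior 0
#' and are rejected by the sampler, exactly as prescribed for the
#' Metropolis-Hastings ratio. A move whose eligible set is empty (or
#' Add-Reticulation at the reticulation cap) returns `ok = FALSE` and the
#' sampler records a rejected iteration.
#'
#' @param net a valid [PhyloNetwork-class] object (current state).
#' @param kind one of `"changeLength"`, `"changeInheritance"`,
#'   `"moveTail"`, `"moveHead"`, `"flipReticulation"`,
#'   `"addReticulation"`, `"deleteReticulation"`.
#' @param config a [moveConfig()] list.
#' @param choices optional forced-choice list (replaces all random draws;
#'   used to replay a proposal or construct its exact reverse).
#' @return a list with elements `ok`, `kind`, `net` (candidate
#'   [PhyloNetwork-class], unvalidated), `logHastings`, `logJacobian`,
#'   and `reverse` (forced choices of the exact reverse proposal).
#' @export
proposeMove <- function(net, kind, config = moveConfig(), choices = NULL) {
  res <- propose_nw(as_nw(net), kind, config, choices)
  if (!res$ok)
    return(list(ok = FALSE, kind = res$kind, net = NULL,
                logHastings = NA_real_, logJacobian = NA_real_))
  list(ok = TRUE, kind = res$kind, net = nw_to_s4(res$nw, check = FALSE),
       logHastings = res$logH, logJacobian = res$logJ, reverse = res$reverse)
}
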