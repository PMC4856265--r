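# Metropolis-Hastings sampling of (network, inheritance probabilities)
# and posterior summaries.

#' Run configuration for the sampler
#'
#' @param iterations total Metropolis-Hastings iterations `N`.
#' @param burnin iterations discarded before storage (default 10% of
#'   `N`).
#' @param thin store every `thin`-th post-burn-in state (default chosen
#'   so about 10^4 states are kept).
#' @param seed RNG seed; identical (data, config, seed) runs are
#'   reproducible.
#' @param prior a [priorConfig()] list.
#' @param moves a [moveConfig()] list.
#' @param init optional initial network ([PhyloNetwork-class] or
#'   extended-Newick string); default is a random tree on the species set
#'   with Exponential(`delta`) branch lengths (the chain adds
#'   reticulations itself).
#' @param species species names; required for prior-only runs
#'   (`data = NULL`), otherwise taken from the data.
#' @return a validated list of class `run_config`.
#' @export
runConfig <- function(iterations = 5e6, burnin = floor(iterations / 10),
                      thin = max(1L, floor((iterations - burnin) / 1e4)),
                      seed = 1L, prior = priorConfig(), moves = moveConfig(),
                      init = NULL, species = NULL) {
  stopifnot(iterations > burnin, burnin >= 0, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed), prior = prior, moves = moves,
                 init = init, species = species),
            class = "run_config")
}

# random starting tree on the species set, Exponential(delta) lengths
random_start_tree <- function(species, delta) {
  n <- length(species)
  species <- sample(species)          # random labeled shape
  lab <- structure(species, names = as.character(seq_len(n)))
  nw <- new_nw(cbind(c(n + 1L, n + 1L), c(1L, 2L)), stats::rexp(2, delta),
               rep(NA_real_, 2), lab[1:2], n + 1L)
  if (n > 2L) for (leaf in 3:n) {
    nw$label <- lab[seq_len(leaf)]
    i <- sample.int(nrow(nw$edge), 1L)
    sp <- nw_split_edge(nw, i, stats::runif(1, 0, nw$len[i]),
                        id = max(nw_ids(nw), n) + 1L)
    nw <- sp$nw
    nw$edge <- rbind(nw$edge, c(sp$node, leaf))
    nw$len <- c(nw$len, stats::rexp(1, delta))
    nw$gamma <- c(nw$gamma, NA_real_)
  }
  nw$label <- lab
  nw
}

#' Sample phylogenetic networks from the posterior
#'
#' The Metropolis-Hastings loop: each iteration selects one of the seven
#' moves, proposes a candidate `(network, gamma)` state, and accepts it
#' with probability `min(1, r)` where `log r` is the sum of the
#' log-likelihood ratio, log-prior ratio, log Hastings ratio and (for the
#' dimension-changing pair) the log Jacobian. Candidates violating the
#' network definition have prior 0 and are always rejected. Pass
#' `data = NULL` to sample from the prior alone (likelihood identically
#' 1), which is the standard sampler-correctness check.
#'
#' @param data a [GeneTreeData-class] object, or `NULL` for a prior-only
#'   run (then `config$species` must be set).
#' @param config a [runConfig()] list.
#' @return a [SampleChain-class] object.
#' @seealso [credibleSet()], [traceSummary()]
#' @export
runChain <- function(data, config = runConfig()) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  prior_only <- is.null(data)
  if (prior_only) {
    species <- config$species
    if (is.null(species))
      stop("prior-only runs need config$species")
  } else {
    stopifnot(is(data, "GeneTreeData"))
    species <- data@species
  }
  levels <- sort(species)

  mcfg <- config$moves
  if (is.null(mcfg$maxReticulations))
    mcfg$maxReticulations <- length(species) - 1L
  pcfg <- config$prior
  if (is.null(mcfg$addLengthRate)) mcfg$addLengthRate <- pcfg$delta

  nw <- if (!is.null(config$init)) {
    x <- config$init
    if (is.character(x)) x <- parseENewick(x)
    as_nw(x)
  } else random_start_tree(species, pcfg$delta)
  if (!setequal(unname(nw$label), species))
    stop("initial network leaves do not match the species set")

  if (!prior_only) {
    prepped <- prep_topos(data@topologies, levels)
    keys <- names(data@topologies)
    W <- do.call(rbind, lapply(data@lociWeights, function(w) {
      out <- numeric(length(keys))
      out[match(names(w), keys)] <- w
      out
    }))
    Wtot <- rowSums(W)
  }
  leaves <- nw_leaf_species(nw, levels)   # leaf ids and labels are stable
  loglik <- function(nw) {
    if (prior_only) 0
    else data_loglik_fast(nw, prepped, levels, W, Wtot, leaves)
  }

  logP <- log_prior_fast(nw, pcfg)
  logL <- loglik(nw)
  if (!is.finite(logP + logL))
    stop("initial state has zero posterior density; supply a different init")

  N <- config$iterations
  nkeep <- (N - config$burnin) %/% config$thin
  rec_iter <- integer(nkeep); rec_key <- character(nkeep)
  rec_newick <- character(nkeep); rec_ll <- numeric(nkeep)
  rec_lp <- numeric(nkeep); rec_move <- character(nkeep)
  rec_acc <- logical(nkeep)
  nprop <- structure(integer(7), names = MOVE_KINDS)
  nacc <- structure(integer(7), names = MOVE_KINDS)
  kept <- 0L

  for (it in seq_len(N)) {
    kind <- select_move_nw(nw, mcfg)
    nprop[kind] <- nprop[kind] + 1L
    pr <- propose_nw(nw, kind, mcfg)
    accepted <- FALSE
    if (pr$ok) {
      lpP <- log_prior_fast(pr$nw, pcfg)
      if (is.finite(lpP)) {
        lpL <- loglik(pr$nw)
        logr <- (lpL - logL) + (lpP - logP) + pr$logH + pr$logJ
        if (is.finite(logr) && log(stats::runif(1)) < logr) {
          nw <- pr$nw; logL <- lpL; logP <- lpP
          accepted <- TRUE
          nacc[kind] <- nacc[kind] + 1L
        }
      }
    }
    if (it > config$burnin && (it - config$burnin) %% config$thin == 0L &&
        kept < nkeep) {
      kept <- kept + 1L
      rec_iter[kept] <- it
      rec_key[kept] <- topology_key_nw(nw)
      rec_newick[kept] <- write_enewick_nw(nw)
      rec_ll[kept] <- logL
      rec_lp[kept] <- logP
      rec_move[kept] <- kind
      rec_acc[kept] <- accepted
    }
  }
  idx <- seq_len(kept)
  new("SampleChain",
      records = data.frame(iteration = rec_iter[idx], key = rec_key[idx],
                           newick = rec_newick[idx], logLik = rec_ll[idx],
                           logPrior = rec_lp[idx], move = rec_move[idx],
                           accepted = rec_acc[idx],
                           stringsAsFactors = FALSE),
      moveStats = data.frame(move = MOVE_KINDS, proposed = as.integer(nprop),
                             accepted = as.integer(nacc),
                             stringsAsFactors = FALSE),
      config = unclass(config))
}

#' Credible set of sampled topologies
#'
#' Distinct topology keys sorted by descending posterior frequency (ties
#' broken lexicographically by key); the returned prefix is the smallest
#' whose cumulative frequency reaches `level`. Branch lengths and
#' inheritance probabilities are marginalized out: membership counts
#' topologies only. The representative network per key is the sampled
#' state with the highest log-posterior. `bestLogLik` supports spotting
#' likelihood-indistinguishable members (best sampled log-likelihoods
#' closer than about 1e-6).
#'
#' @param chain a [SampleChain-class] object with at least one record.
#' @param level credible level (default 0.95).
#' @return data.frame with columns `key`, `frequency`, `newick`
#'   (representative, extended Newick), `bestLogLik`.
#' @export
credibleSet <- function(chain, level = 0.95) {
  stopifnot(is(chain, "SampleChain"), level > 0, level <= 1)
  rec <- chain@records
  if (!nrow(rec)) stop("empty chain: nothing was stored")
  tab <- table(rec$key)
  freq <- as.numeric(tab) / nrow(rec)
  keys <- names(tab)
  ord <- order(-freq, keys)
  keys <- keys[ord]; freq <- freq[ord]
  ncs <- which(cumsum(freq) >= level - 1e-12)[1]
  if (is.na(ncs)) ncs <- length(keys)
  keys <- keys[seq_len(ncs)]; freq <- freq[seq_len(ncs)]
  rep_newick <- character(ncs); best_ll <- numeric(ncs)
  for (i in seq_len(ncs)) {
    sub <- rec[rec$key == keys[i], ]
    j <- which.max(sub$logLik + sub$logPrior)
    rep_newick[i] <- sub$newick[j]
    best_ll[i] <- max(sub$logLik)
  }
  data.frame(key = keys, frequency = freq, newick = rep_newick,
             bestLogLik = best_ll, stringsAsFactors = FALSE)
}

#' Trace and acceptance-rate summary
#'
#' @param chain a [SampleChain-class] object.
#' @return list with `trace` (data.frame: iteration, logPosterior) and
#'   `acceptance` (data.frame: move, proposed, accepted, rate); both
#'   writable as delimited text for plotting.
#' @export
traceSummary <- function(chain) {
  stopifnot(is(chain, "SampleChain"))
  rec <- chain@records
  ms <- chain@moveStats
  ms$rate <- ifelse(ms$proposed > 0, ms$accepted / ms$proposed, NA_real_)
  list(trace = data.frame(iteration = rec$iteration,
                          logPosterior = rec$logLik + rec$logPrior),
       acceptance = ms)
}
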