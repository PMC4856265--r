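# Priors over networks and inheritance probabilities.

#' Prior configuration
#'
#' The network prior factorizes into a reticulation-count term, a
#' branch-length term and a topology term:
#' Poisson(`nu`) on the number of reticulation nodes divided by the
#' topology count `T[n,m]`, i.i.d. Exponential(`delta`) on branch lengths,
#' and Exponential(`eta`) on a topology statistic. With `eta = 0`
#' (default) the topology term is omitted. The statistic, when enabled, is
#' the "reticulation span": the summed length of the two edges entering
#' each reticulation node, a length-coupled complexity penalty.
#'
#' @param nu Poisson mean for the reticulation count, `> 0`.
#' @param delta Exponential rate for branch lengths (per coalescent
#'   unit), `> 0`.
#' @param eta Exponential rate for the topology statistic, `>= 0`;
#'   0 disables the term.
#' @param topologyStatistic name of the statistic; only
#'   `"reticulation-span"` is built in.
#' @param tNmMode how `T[n,m]` is evaluated: `"auto"` enumerates exactly
#'   within the small-case guard and uses the combinatorial surrogate
#'   outside it; `"constant"` drops the factor; see [countTopologies()].
#' @return a validated list of class `prior_config`.
#' @export
priorConfig <- function(nu = 1.0, delta = 1.0, eta = 0.0,
                        topologyStatistic = "reticulation-span",
                        tNmMode = c("auto", "enumerate", "constant")) {
  stopifnot(nu > 0, delta > 0, eta >= 0)
  topologyStatistic <- match.arg(topologyStatistic)
  structure(list(nu = nu, delta = delta, eta = eta,
                 topologyStatistic = topologyStatistic,
                 tNmMode = match.arg(tNmMode)),
            class = "prior_config")
}

# memoized T_{n,m} lookup without argument checking (MCMC hot path)
tnm_fast <- function(n, m, mode) {
  if (mode == "constant") return(1)
  if (mode == "auto" && (n > 5L || m > 2L)) return(tnm_surrogate(n, m))
  key <- sprintf("%d_%d", n, m)
  val <- .tnm_cache[[key]]
  if (!is.null(val)) return(val)
  count_topologies_impl(n, m, mode)
}

# validity + log-prior in one pass, used inside the MCMC loop; agrees
# with logPriorNetwork + logPriorInheritance on every input
log_prior_fast <- function(nw, cfg) {
  m <- cpp_check_network(nw$edge, nw$root, length(nw$label), nw$gamma, nw$len)
  if (m < 0L) return(-Inf)
  lp <- stats::dpois(m, cfg$nu, log = TRUE) -
    log(tnm_fast(length(nw$label), m, cfg$tNmMode)) +
    length(nw$len) * log(cfg$delta) - cfg$delta * sum(nw$len)
  if (cfg$eta > 0)
    lp <- lp + stats::dexp(retic_span(nw), cfg$eta, log = TRUE)
  lp
}

retic_span <- function(nw) {
  re <- nw_retic_edges(nw)
  if (!length(re)) 0 else sum(nw$len[re])
}

log_prior_nw <- function(nw, cfg) {
  if (!nw_is_valid(nw)) return(-Inf)
  m <- length(nw_retic_nodes(nw))
  n <- nw_ntaxa(nw)
  lp <- stats::dpois(m, cfg$nu, log = TRUE) -
    log(count_topologies_impl(n, m, cfg$tNmMode)) +
    sum(stats::dexp(nw$len, cfg$delta, log = TRUE))
  if (cfg$eta > 0)
    lp <- lp + stats::dexp(retic_span(nw), cfg$eta, log = TRUE)
  lp
}

#' Log-prior of a candidate network
#'
#' Evaluates the network prior; any candidate violating the phylogenetic
#' network definition (cycle, parallel edges, multiple roots, degree or
#' length violations -- see [validateNetwork()]) receives prior 0, i.e.
#' `-Inf` on the log scale. This is how raw proposal-move output is
#' filtered: invalid candidates are always rejected by the sampler.
#'
#' @param net a [PhyloNetwork-class] object or candidate list.
#' @param config a [priorConfig()] list.
#' @return log prior density (extended real; `-Inf` for invalid input).
#' @export
logPriorNetwork <- function(net, config = priorConfig()) {
  log_prior_nw(as_nw(net), config)
}

#' Log-prior of the inheritance probabilities
#'
#' Uniform on `[0, 1]` for each reticulation node: 0 when every
#' inheritance probability lies in `[0, 1]`, `-Inf` otherwise. The empty
#' map (a tree) has log-prior 0.
#'
#' @param gamma a [PhyloNetwork-class] object (its inheritance
#'   probabilities are read off) or a numeric vector of probabilities.
#' @return 0 or `-Inf`.
#' @export
logPriorInheritance <- function(gamma) {
  if (is(gamma, "PhyloNetwork") || is.list(gamma)) {
    nw <- as_nw(gamma)
    gamma <- nw$gamma[nw_retic_edges(nw)]
  }
  gamma <- gamma[!is.na(gamma)]
  if (!length(gamma)) return(0)
  if (all(gamma >= 0 & gamma <= 1)) 0 else -Inf
}
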