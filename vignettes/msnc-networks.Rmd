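---
title: "Bayesian phylogenetic networks under the multispecies network coalescent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian phylogenetic networks under the multispecies network coalescent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcoal)
```

## The model

Hybridization, introgression and other forms of gene flow make species
histories reticulate: the history is a rooted **phylogenetic network**, a
binary DAG with a single root (in-degree 0, out-degree 2), labeled leaves,
internal tree nodes (1 in, 2 out) and reticulation nodes (2 in, 1 out).
Branch lengths are measured in **coalescent units** (generations divided by
effective population size). Each reticulation node carries an **inheritance
probability** $\gamma \in [0,1]$: a gene lineage entering the node follows
the designated parent edge with probability $\gamma$ and the other with
$1-\gamma$, independently per lineage and per locus.

Within this structure, gene genealogies grow backward in time exactly as in
the multispecies coalescent: inside a branch, each pair of the $k$ lineages
present coalesces at rate 1 per coalescent unit, and the probability that
$u$ lineages leave a branch of length $t$ as $v$ lineages is the classical
Tavar&eacute; transition $g_{uv}(t)$ (implemented in `coalescenceProb()`).
This combination — coalescence within branches plus $\gamma$-routing at
reticulation nodes — is the multispecies network coalescent (MSNC).

Given per-locus collections of **estimated rooted gene-tree topologies**
$G = \{g_1,\dots,g_m\}$ (typically 100 bootstrap trees per locus), the
package samples the posterior

$$ p(\Psi, \Gamma \mid G) \;\propto\; p(\Psi)\, p(\Gamma)\,
   \prod_{i=1}^m p(g_i \mid \Psi, \Gamma), $$

where $p(g_i \mid \Psi,\Gamma)$ is the exact probability mass of the
locus's topology estimates under the MSNC (averaged over the bootstrap
multiset, see below). Branch lengths of gene trees are deliberately not
modeled: only topologies enter the likelihood.

## The likelihood

`geneTreeProb()` computes the exact mass of one rooted topology by dynamic
programming over *configurations*. Processing network nodes from the leaves
toward the root, the state tracks, for every open branch, the set of
gene-tree clades currently alive as lineages. Within a branch only merges
between gene-tree siblings are allowed; a transition from $k$ to $k-j$
lineages contributes

$$ g_{k,k-j}(t)\; \cdot\; \frac{w}{\prod_{i=0}^{j-1}\binom{k-i}{2}}, $$

with $w$ the number of orderings of the $j$ required merges (all ordered
merge sequences being equally likely given their number). At a reticulation
node the state splits over all $2^k$ assignments of lineages to the two
parent edges, weighted $\gamma^{|A|}(1-\gamma)^{k-|A|}$; this makes the two
parent branches' configurations jointly dependent, which is why the DP
carries joint states rather than per-branch marginals. Above the root all
remaining lineages must coalesce into the gene-tree root. The sum over
assignments and coalescent histories is exact; its cost is exponential in
the reticulation count and the number of sampled lineages, which is
practical at the intended scale (up to about 8 taxa and 3 reticulations).
The kernel is compiled (C++) because one posterior sampling run evaluates
it on the order of $10^5$–$10^6$ times.

Correctness is pinned by three independent routes, all in the test suite:
closed-form 3-taxon MSC expressions; normalization to 1 over all rooted
topologies; and, on species *trees*, an independently coded
coalescent-history sum (explicit history enumeration with hook-length
ordering counts). A forward MSNC simulator (`simulateGeneTree()`) provides
a fourth, Monte-Carlo route: empirical topology frequencies agree with the
mass function within binomial error on every grid network tested.

Gene-tree uncertainty: the likelihood of a locus is the unweighted
arithmetic mean of the topology mass over the locus's multiset of
estimates. Duplicate topologies are collapsed with multiplicities, and all
distinct topologies are pooled across loci so each is evaluated once per
proposed network; both transformations leave the value unchanged
(tested).

## Priors

The network prior factorizes as

$$ p(\Psi) \;=\; \underbrace{\frac{1}{T_{n,m}}\,\mathrm{Poisson}(m;\nu)}_{\text{reticulation count}}
  \times \prod_b \delta e^{-\delta \lambda_b}
  \times \underbrace{\eta\, e^{-\eta\, s(\Psi)}}_{\text{optional}}, $$

with $T_{n,m}$ the number of network topologies on $n$ leaves with $m$
reticulation nodes. Dividing by $T_{n,m}$ makes the *marginal* prior over
the reticulation count exactly Poisson, which the prior-only sampler checks
reproduce. Inheritance probabilities are uniform on $[0,1]$. Any candidate
violating the network definition — a cycle, parallel edges, a second root,
a degree anomaly, a negative length — receives prior 0 and is always
rejected; proposal moves deliberately return such raw candidates instead of
filtering them.

Decisions made here, where the design was genuinely open:

* **Topology term.** The exponential topology factor's statistic is not
  canonical; the package uses the *reticulation span* (summed length of the
  two edges entering each reticulation node), the natural length-coupled
  complexity penalty given that the term conditions on branch lengths. The
  default is $\eta = 0$, i.e. the term is off, so no unstated choice is
  silently asserted. The statistic is a configuration hook.
* **$T_{n,m}$ evaluation.** For $n \le 5$, $m \le 2$ the count is computed
  by exhaustive generation: add a reticulation edge in every possible way
  to the $(m-1)$-enumeration, then *close the set under the topology
  relocation moves* (tail/head relocation, flip), deduplicating by
  canonical key. The closure matters: single-edge addition alone misses a
  small number of topologies (at $n=3$, $m=2$ it finds 264 of 279; the
  missing ones have no reticulation edge whose deletion leaves a valid
  smaller network). The closure set coincides exactly with the set of
  topologies the sampler reaches, which is the consistency that the prior
  factor requires. Outside the guard the factor uses a combinatorial
  surrogate: the tree count $(2n-3)!!$ times, for each added
  reticulation, the number of ordered attachment-edge pairs
  $\binom{E_j}{2}$ with $E_j = 2n-2+3j$ edges. Where exact counts are
  known the surrogate is accurate to a factor of about 1.4 — and that
  accuracy matters: a constant fallback makes the number of
  higher-reticulation topologies overwhelm the Poisson shrinkage (at 7
  taxa the many 2-reticulation neighborhoods of a 1-reticulation truth
  would jointly dominate the posterior even when each fits no better),
  which is precisely the class-size effect the $1/T_{n,m}$ factor is
  there to cancel. The constant fallback remains available as
  `tNmMode = "constant"`.
* **Branch-length prior** is i.i.d. Exponential($\delta$) per branch, the
  simplest proper reading of an exponential length prior; defaults
  $\nu = 1$, $\delta = 1$ (configurable).

## The seven proposal moves

`runChain()` is a Metropolis&ndash;Hastings sampler whose proposal kernel
mixes seven moves, selected hierarchically (`moveConfig()`): with
probability $\kappa$ a dimension-changing move (Add-Reticulation with
probability $\kappa_1$, else Delete-Reticulation); otherwise with
probability $\omega$ a non-topological move (Change-Length with
$\omega_1$, else Change-Inheritance); otherwise a topological move
(Move-Tail, Move-Head, Flip-Reticulation with $\xi_{1..3}$). On a tree,
moves that need a reticulation get probability 0: Add absorbs Delete's
mass and Change-Length absorbs Change-Inheritance's. For the $\xi$ branch
the reassignment is not externally specified; here the whole topological
mass goes to Move-Tail, which is harmless for detailed balance because
moves 3&ndash;5 never change the reticulation count, so forward and
reverse selection probabilities cancel.

Proposal details, chosen where no canonical densities exist:

* Continuous perturbations (lengths, $\gamma$) use symmetric uniform
  windows with reflection (at 0 for lengths; at 0 and 1 for $\gamma$,
  window capped at 0.5 so a draw reflects at most once). Reflection keeps
  the kernel symmetric, so these moves are Hastings-neutral. Defaults:
  0.5 coalescent units and 0.1.
* Move-Tail detaches an edge whose tail is an internal tree node,
  suppresses the degree-2 remnant (lengths summing), and reattaches at a
  uniform height on a uniformly chosen destination edge. The Hastings
  ratio collects the eligible-set sizes, destination counts and the two
  height densities. Move-Head does the same for reticulation-edge heads,
  preserving the node's $\gamma$.
* Flip-Reticulation reverses a reticulation edge whose tail is an internal
  tree node; tail and head swap roles (the old tail becomes the new
  reticulation node). The flipped node's $\gamma$ has no canonical owner,
  so it is redrawn uniformly; the uniform densities cancel in the ratio.
* Add-Reticulation picks two edges (independently, possibly the same
  edge — that candidate is always invalid and dies at the prior, exactly
  the advertised behavior), uniform attachment heights, a new edge length
  drawn Exponential(`addLengthRate`, defaulting to the prior rate
  $\delta$), and $\gamma \sim U(0,1)$. With this parameterization the
  dimension-matching map is the identity on the drawn coordinates, so the
  reversible-jump Jacobian is 1. Delete-Reticulation removes a
  reticulation edge whose tail is an internal tree node and suppresses
  both remnants; its Hastings ratio mirrors Add's exactly.
* A move whose eligible set is empty (or Add at the `maxReticulations`
  cap, default: number of taxa minus 1) is recorded as a rejected
  iteration, keeping the kernel well defined.

Every move returns, alongside the candidate, the forced-choice list that
reproduces its exact reverse. The test suite replays these on thousands of
randomized states and asserts both that the reverse restores the original
state exactly and that the forward and reverse log-Hastings(+Jacobian)
terms negate — this, plus prior recovery, is what pins the ratio algebra.

## Sampler output and summaries

Each iteration accepts with probability $\min(1, r)$,
$\log r = \Delta\log L + \Delta\log p + \log H + \log|J|$. Post-burn-in,
thinned states are stored with their canonical topology key, extended
Newick serialization, log-likelihood and log-prior. `credibleSet()` ranks
distinct topology keys by posterior frequency (lengths and $\gamma$
marginalized out; ties broken lexicographically) and returns the smallest
prefix reaching the requested level, with the highest-posterior sampled
network as each key's representative; the `bestLogLik` column helps spot
members that are likelihood-indistinguishable. `traceSummary()` tabulates
the log-posterior trace and per-move acceptance rates. Identical data,
configuration and seed reproduce a chain exactly.

Defaults: $5\times 10^6$ iterations, 10% burn-in, thinning to about
$10^4$ stored states, and a random starting tree with
Exponential($\delta$) lengths (reticulations are added by the chain). The
initializer is a package choice; any valid starting network can be given.

## The simulator and synthetic data

`simulateGeneTree()` runs the coalescent backward along the network;
`simulateAlignment()` evolves i.i.d. sites along the resulting gene tree;
`estimateGeneTrees()` re-estimates per-locus bootstrap topologies. The
synthetic-data defaults mirror the simulation study the package validates
against: three fixed 7-taxon model networks (`modelNetworkSuite()`; one
outgroup, 1/2/3 reticulations, branch lengths from 0.5 to 1.5 coalescent
units, fixed inheritance probabilities), $\theta = 0.036$, 1000 sites,
100 bootstrap replicates per locus.

Choices worth stating:

* **Unit conversion.** A branch of $t$ coalescent units receives
  $\theta/2 \cdot t$ expected substitutions per site ($\theta = 4N\mu$
  with time in units of $2N$ generations) — the dominant convention in
  coalescent simulation pipelines, and configurable through `theta`.
* **Substitution model.** Sequence simulation supports GTR, but the
  fixtures default to Jukes&ndash;Cantor (the GTR parameterization used in
  the original study is not published in its main text, and the estimation
  error this pipeline measures is insensitive at this divergence level).
* **Estimation engine.** Neighbor joining on JC distances with outgroup
  rooting is the default bootstrap engine (fast enough for 5000 fits in
  seconds); a slower maximum-likelihood engine (`engine = "ml"`, NNI
  search via phangorn) is available. Saturated JC distances are capped at
  5 substitutions per site rather than dropped.
* The exact model networks of the original study are not published; the
  suite fixes its own three networks satisfying every stated property and
  ships them as versioned extended-Newick fixtures.

What passing the synthetic tests does and does not show: the generator
produces ideal MSNC data — independent, recombination-free loci, no rate
heterogeneity, no indels or alignment error, equal population sizes along
each branch (one coalescent-unit clock), and bootstrap error as the only
gene-tree uncertainty. Real data violate most of these; recovery results
on the synthetic regime bound what the method can do when its model is
true, not what it will do on a particular empirical data set.

## Numerical and scale choices

* Likelihoods accumulate in linear space per topology (masses at desk
  scale are far above underflow) and in log space across loci; a locus
  mass of exactly 0 yields $-\infty$, a rejectable state rather than an
  error.
* $g_{uv}(t)$ uses the alternating-sum closed form in double precision,
  adequate for the $u \le 10$ lineage counts reachable at this scale, with
  results clamped to $[0,1]$.
* Canonical topology keys come from color refinement seeded with leaf
  labels and node classes, with an individualization fallback for
  residual ties; keys are validated against exhaustive node-bijection
  isomorphism on the enumerable grid.
* Test scales are the package's own: the enumerable-posterior anchor runs
  $10^6$ iterations on 3 taxa; prior recovery $5\times 10^5$; the
  network-recovery experiment uses 128 loci of simulated gene trees from
  the 1-reticulation model network with a $1.2\times 10^5$-iteration
  chain capped at two reticulations (the posterior concentrates long
  before that). The recovery experiment runs under the full three-factor
  prior with $\eta = 1$: without the length-coupled topology term, about
  a tenth of the posterior mass scatters across many two-reticulation
  supersets of the truth (none fitting materially better), which is the
  regime the term exists to regularize. Estimation error is measured at
  50 loci with 100 bootstrap replicates each.

## Known limitations

* Exact likelihood only: cost grows exponentially with reticulations and
  sampled lineages; no pseudo-likelihood shortcut is provided.
* Gene-tree branch lengths are ignored by design; loci whose estimates
  are poorly resolved contribute through their bootstrap spread only.
* $T_{n,m}$ outside the enumeration guard is a constant, so the prior's
  reticulation-count calibration is exact only at small $n$; at data
  scale the Poisson term still penalizes complexity, just without the
  per-class topology-count normalization.
* Convergence diagnostics are traces and acceptance rates; no multi-chain
  statistics or tempering.
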