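# The MSNC gene-tree-topology likelihood.

test_that("coalescence probabilities follow the classical closed forms", {
  expect_identical(coalescenceProb(1, 1, 7.3), 1)
  expect_identical(coalescenceProb(1, 1, Inf), 1)
  for (t in c(0.1, 1, 10))
    expect_equal(coalescenceProb(2, 1, t), 1 - exp(-t), tolerance = 1e-12)
  # normalization over v for several u and t
  for (u in 2:6)
    for (t in c(0.1, 1, 10))
      expect_equal(sum(vapply(1:u, function(v) coalescenceProb(u, v, t), 0)),
                   1, tolerance = 1e-10)
  expect_identical(coalescenceProb(4, 4, 0), 1)
  expect_identical(coalescenceProb(5, 1, Inf), 1)
  expect_error(coalescenceProb(2, 3, 1), "v <= u")
  expect_error(coalescenceProb(2, 0, 1), "v <= u")
  # the compiled copy used by the likelihood core agrees
  for (u in 1:6) for (v in 1:u) for (t in c(0.2, 1.5))
    expect_equal(coalescenceProb(u, v, t), netcoal:::cpp_coal_prob(u, v, t),
                 tolerance = 1e-12)
})

test_that("3-taxon masses match the closed-form MSC expressions", {
  for (t in c(0.2, 0.8, 2.5)) {
    net <- parseENewick(sprintf("((A:1,B:1):%g,C:2);", t))
    expect_equal(geneTreeProb(net, "((A,B),C);"), 1 - 2 / 3 * exp(-t),
                 tolerance = 1e-12)
    expect_equal(geneTreeProb(net, "((A,C),B);"), exp(-t) / 3,
                 tolerance = 1e-12)
    expect_equal(geneTreeProb(net, "((B,C),A);"), exp(-t) / 3,
                 tolerance = 1e-12)
  }
})

test_that("masses normalize over all rooted topologies on the test grid", {
  set.seed(11)
  grids <- list(
    list(labels = c("A", "B", "C"), m = 0),
    list(labels = c("A", "B", "C"), m = 1),
    list(labels = c("A", "B", "C", "D"), m = 0),
    list(labels = c("A", "B", "C", "D"), m = 1))
  for (g in grids) {
    pool <- netcoal:::enumerate_networks_nw(g$labels, g$m)
    topos <- all_tree_phylos(g$labels)
    for (rep in 1:3) {
      nw <- randomize_nw(pool[[sample.int(length(pool), 1)]])
      net <- netcoal:::nw_to_s4(nw)
      tot <- sum(vapply(topos, function(tp) geneTreeProb(net, tp), 0))
      expect_equal(tot, 1, tolerance = 1e-8)
    }
  }
  # with multiple samples per species (5 lineages total)
  net <- parseENewick("((A:1,(B:0.5)#H1:0.5::0.3):1,(#H1:0.5::0.7,C:1):1);")
  map <- c(A_1 = "A", A_2 = "A", B_1 = "B", B_2 = "B", C = "C")
  topos5 <- all_tree_phylos(names(map))
  tot <- sum(vapply(topos5, function(tp) geneTreeProb(net, tp, map), 0))
  expect_equal(tot, 1, tolerance = 1e-8)
})

test_that("tree networks reduce to the independent MSC oracle", {
  set.seed(13)
  trees4 <- netcoal:::enumerate_trees_nw(c("A", "B", "C", "D"))
  topos <- all_tree_phylos(c("A", "B", "C", "D"))
  for (rep in 1:4) {
    nw <- randomize_nw(trees4[[sample.int(15, 1)]])
    net <- netcoal:::nw_to_s4(nw)
    for (tp in topos[sample.int(15, 5)])
      expect_equal(geneTreeProb(net, tp), msc_tree_prob(nw, tp),
                   tolerance = 1e-10)
  }
})

test_that("gamma = 1 reduces to the displayed tree", {
  net1 <- parseENewick("((A:1,(B:0.5)#H1:0.5::1):1,(#H1:0.5::0,C:1):1);")
  shown <- parseENewick("((A:1,B:1):1,C:1);")
  for (tp in all_tree_phylos(c("A", "B", "C")))
    expect_equal(geneTreeProb(net1, tp), geneTreeProb(shown, tp),
                 tolerance = 1e-12)
  # long separating branches: mass approaches the gamma-weighted mixture
  # of the two displayed trees' MSC masses
  long <- parseENewick(paste0("((A:20,(B:20)#H1:20::0.3):20,",
                              "(#H1:20::0.7,C:20):20);"))
  d1 <- parseENewick("((A:40,B:60):20,C:40);")    # B tracks the A side
  d2 <- parseENewick("(A:40,(B:60,C:40):20);")    # B tracks the C side
  for (tp in all_tree_phylos(c("A", "B", "C"))) {
    mix <- 0.3 * geneTreeProb(d1, tp) + 0.7 * geneTreeProb(d2, tp)
    expect_equal(geneTreeProb(long, tp), mix, tolerance = 1e-4)
  }
})

test_that("a single sampled lineage has mass 1", {
  net <- parseENewick("((A:1,(B:0.5)#H1:0.5::0.3):1,(#H1:0.5::0.7,C:1):1);")
  one <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = "b",
                        edge.length = 1, Nnode = 1L), class = "phylo")
  expect_equal(geneTreeProb(net, one, c(b = "B")), 1, tolerance = 1e-12)
})

test_that("locus likelihood is the multiset mean, invariant to dedup", {
  net <- parseENewick("((A:1,B:1):0.8,C:2);")
  g1 <- "((A,B),C);"; g2 <- "((A,C),B);"
  m1 <- geneTreeProb(net, g1); m2 <- geneTreeProb(net, g2)
  expect_equal(locusLikelihood(net, rep(list(g1), 100)), m1, tolerance = 1e-12)
  expect_equal(locusLikelihood(net, c(rep(list(g1), 50), rep(list(g2), 50))),
               (m1 + m2) / 2, tolerance = 1e-12)
  expect_equal(locusLikelihood(net, c(rep(list(g1), 30), rep(list(g2), 70))),
               0.3 * m1 + 0.7 * m2, tolerance = 1e-12)
})

test_that("multi-locus log-likelihood pools topologies without changing values", {
  set.seed(17)
  net <- parseENewick("(((A:0.7,B:0.4):0.5,C:1.2):0.3,D:2);")
  topos <- all_tree_phylos(c("A", "B", "C", "D"))
  loci <- lapply(1:6, function(i) lapply(sample.int(15, 8, TRUE),
                                         function(j) topos[[j]]))
  data <- makeGeneTreeData(loci)
  cached <- dataLogLik(net, data)
  naive <- sum(vapply(loci, function(l) log(locusLikelihood(net, l)), 0))
  expect_equal(cached, naive, tolerance = 1e-12)
  # m identical single-tree loci give m * log(mass)
  d2 <- makeGeneTreeData(rep(list(list("((A,B),(C,D));")), 5))
  expect_equal(dataLogLik(net, d2),
               5 * log(geneTreeProb(net, "((A,B),(C,D));")),
               tolerance = 1e-12)
})

test_that("every topology keeps positive mass on finite-length networks", {
  set.seed(19)
  pool <- netcoal:::enumerate_networks_nw(c("A", "B", "C", "D"), 1)
  topos <- all_tree_phylos(c("A", "B", "C", "D"))
  for (rep in 1:3) {
    nw <- randomize_nw(pool[[sample.int(length(pool), 1)]])
    net <- netcoal:::nw_to_s4(nw)
    masses <- vapply(topos, function(tp) geneTreeProb(net, tp), 0)
    expect_true(all(masses > 0))
    # hence any data set has finite log-likelihood
    data <- makeGeneTreeData(list(lapply(topos[1:4], identity)))
    expect_true(is.finite(dataLogLik(net, data)))
  }
})

test_that("unmapped alleles and invalid trees raise errors", {
  net <- parseENewick("((A:1,B:1):0.8,C:2);")
  expect_error(geneTreeProb(net, "((A,B),X);"), "not a leaf")
  expect_error(geneTreeProb(net, "((a,b),c);", c(a = "A", b = "B")),
               "missing from the taxon map")
  expect_error(geneTreeProb(net, "(A,B,C);"), "binary")
})
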