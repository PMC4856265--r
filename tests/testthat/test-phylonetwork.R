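# Network structure, extended-Newick I/O, validation, canonical keys,
# and topology counting.

test_that("parsing handles trees, reticulations and round trips", {
  tr <- parseENewick("((A:1.0,B:1.0):1.0,C:2.0);")
  expect_s4_class(tr, "PhyloNetwork")
  expect_identical(nReticulations(tr), 0L)
  expect_identical(taxa(tr), c("A", "B", "C"))

  net <- parseENewick("((A:1,(B:0.5)#H1:0.5::0.3):1,(#H1:0.5::0.7,C:1):1);")
  expect_identical(nReticulations(net), 1L)
  inh <- inheritance(net)
  expect_equal(sort(inh$gamma), c(0.3, 0.7))

  # round trip is isomorphic (brute-force check), with lengths preserved
  net2 <- parseENewick(writeENewick(net))
  expect_true(iso_networks(net, net2))
  expect_equal(sort(branchLengths(net2)), sort(branchLengths(net)))

  # canonical child ordering: A before B on a 2-leaf tree
  two <- parseENewick("(B:1,A:2);")
  expect_match(writeENewick(two), "^\\(A:")
  # a 1-reticulation network serializes with exactly two #H1 tokens
  expect_identical(lengths(regmatches(writeENewick(net),
                                      gregexpr("#H1", writeENewick(net)))),
                   2L)
})

test_that("parser rejects malformed input with informative errors", {
  expect_error(parseENewick("((A,B),C)"), "';'")
  expect_error(parseENewick("((A:1,B:1):1,A:1);"), "duplicate leaf label 'A'")
  expect_error(parseENewick("((A,(B)#H1),(#H1,(#H1,C)));"), "#H1")
  expect_error(parseENewick("((A,(B)#H1::0.3),C);"), "appears 1")
  expect_error(parseENewick("((A:x,B:1):1,C:1);"), "not a number")
})

test_that("round trip holds over a random move-generated corpus", {
  set.seed(71)
  cfg <- moveConfig(kappa = 0.4, maxReticulations = 3)
  cfg$addLengthRate <- 1
  nw <- netcoal:::random_start_tree(c("A", "B", "C", "D", "E", "F"), 1)
  checked <- 0L
  for (i in 1:400) {
    kind <- netcoal:::select_move_nw(nw, cfg)
    pr <- netcoal:::propose_nw(nw, kind, cfg)
    if (pr$ok && netcoal:::nw_is_valid(pr$nw)) nw <- pr$nw
    if (i %% 20 == 0) {
      back <- netcoal:::parse_enewick_nw(netcoal:::write_enewick_nw(nw))
      expect_identical(netcoal:::topology_key_nw(back),
                       netcoal:::topology_key_nw(nw))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 20L)
})

test_that("validate detects every injected defect kind and accepts valid nets", {
  net <- parseENewick("((A:1,(B:0.5)#H1:0.5::0.3):1,(#H1:0.5::0.7,C:1):1);")
  expect_identical(nrow(validateNetwork(net)), 0L)

  base <- nwx(net)
  # cycle: redirect one in-edge of the reticulation node to come from its
  # own child, closing a directed loop
  bad <- base
  r <- netcoal:::nw_retic_nodes(bad)[1]
  er <- which(bad$edge[, 2] == r)[1]
  z <- bad$edge[which(bad$edge[, 1] == r), 2]
  bad$edge[er, 1] <- z
  expect_true("cycle" %in% validateNetwork(bad)$kind)

  # parallel edge
  bad <- base
  bad$edge <- rbind(bad$edge, bad$edge[1, ])
  bad$len <- c(bad$len, 1)
  bad$gamma <- c(bad$gamma, NA_real_)
  expect_true("parallel-edge" %in% validateNetwork(bad)$kind)

  # two in-degree-0 nodes
  bad <- base
  drop <- which(bad$edge[, 1] == bad$root)[1]
  keep <- setdiff(seq_len(nrow(bad$edge)), drop)
  bad2 <- bad
  bad2$edge <- bad$edge[keep, , drop = FALSE]
  bad2$len <- bad$len[keep]
  bad2$gamma <- bad$gamma[keep]
  expect_true("multiple-roots" %in% validateNetwork(bad2)$kind)

  # negative branch length
  bad <- base
  bad$len[2] <- -0.5
  expect_true("negative-length" %in% validateNetwork(bad)$kind)

  # degree violation: leaf with two parents
  bad <- base
  leaf <- as.integer(names(bad$label))[1]
  bad$edge <- rbind(bad$edge, c(bad$root, leaf))
  bad$len <- c(bad$len, 1)
  bad$gamma <- c(bad$gamma, NA_real_)
  expect_true("degree-violation" %in% validateNetwork(bad)$kind)

  # the fast in-chain check agrees with the full validator on all of these
  for (cand in list(base, bad2, bad)) {
    fast <- netcoal:::cpp_check_network(cand$edge, cand$root,
                                        length(cand$label), cand$gamma,
                                        cand$len) >= 0L
    expect_identical(fast, nrow(validateNetwork(cand)) == 0L)
  }
})

test_that("canonical keys ignore ids, lengths and gammas", {
  s <- "((A:1,(B:0.5)#H1:0.5::0.3):1,(#H1:0.5::0.7,C:1):1);"
  net <- parseENewick(s)
  # permute internal ids
  nw <- nwx(net)
  ids <- netcoal:::nw_ids(nw)
  shift <- max(ids) + 5L
  nw2 <- nw
  internal <- setdiff(ids, as.integer(names(nw$label)))
  for (v in rev(internal)) {
    nw2$edge[nw2$edge == v] <- v + shift
    if (nw2$root == v) nw2$root <- v + shift
  }
  expect_identical(netcoal:::topology_key_nw(nw2),
                   netcoal:::topology_key_nw(nw))
  # different lengths / inheritance probabilities
  s2 <- "((A:7,(B:0.1)#H1:2::0.9):4,(#H1:3::0.1,C:5):6);"
  expect_identical(topologyKey(parseENewick(s2)), topologyKey(net))
  # distinct reticulation placements get distinct keys, per the iso oracle
  a <- parseENewick("((A:1,(B:1)#H1:1::0.5):1,(#H1:1::0.5,C:1):1);")
  b <- parseENewick("(((A:1)#H1:1::0.5,B:1):1,(#H1:1::0.5,C:1):1);")
  expect_false(iso_networks(a, b))
  expect_false(topologyKey(a) == topologyKey(b))
})

test_that("canonical key agrees with brute-force isomorphism on enumerations", {
  set.seed(5)
  nets <- c(netcoal:::enumerate_networks_nw(c("A", "B", "C"), 0),
            netcoal:::enumerate_networks_nw(c("A", "B", "C"), 1))
  keys <- vapply(nets, netcoal:::topology_key_nw, "")
  # all pairs on 3 leaves, m <= 1
  for (i in seq_along(nets)) {
    for (j in seq_len(i - 1L)) {
      expect_identical(keys[i] == keys[j], iso_networks(nets[[i]], nets[[j]]),
                       info = sprintf("pair (%d, %d)", i, j))
    }
  }
  # enumerations produce pairwise-distinct keys, so distinctness must agree
  expect_identical(anyDuplicated(keys), 0L)
  # sampled pairs on 4 leaves (trees and 1-reticulation networks)
  nets4 <- c(netcoal:::enumerate_networks_nw(c("A", "B", "C", "D"), 0),
             netcoal:::enumerate_networks_nw(c("A", "B", "C", "D"), 1))
  keys4 <- vapply(nets4, netcoal:::topology_key_nw, "")
  expect_identical(anyDuplicated(keys4), 0L)
  idx <- cbind(sample.int(length(nets4), 150, TRUE),
               sample.int(length(nets4), 150, TRUE))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    expect_identical(keys4[i] == keys4[j], iso_networks(nets4[[i]], nets4[[j]]),
                     info = sprintf("4-leaf pair (%d, %d)", i, j))
  }
})

test_that("topology counts match closed forms and the frozen oracle values", {
  # rooted binary trees: (2n-3)!!
  expect_identical(countTopologies(2, 0, "enumerate"), 1L)
  expect_identical(countTopologies(3, 0, "enumerate"), 3L)
  expect_identical(countTopologies(4, 0, "enumerate"), 15L)
  expect_identical(countTopologies(5, 0, "enumerate"), 105L)
  # frozen brute-force enumeration value
  expect_identical(countTopologies(2, 1, "enumerate"), 2L)
  # guard behavior
  expect_error(countTopologies(7, 1, "enumerate"), "unsupported")
  # out-of-guard auto mode: surrogate = trees x ordered edge pairs
  expect_identical(countTopologies(7, 1, "auto"), 10395 * 66)
  expect_identical(countTopologies(3, 1, "constant"), 1)
})
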