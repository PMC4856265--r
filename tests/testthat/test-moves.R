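# The seven proposal moves: selection scheme, Hastings ratios,
# reversibility, and structural guarantees.

move_pool <- function() {
  c(netcoal:::enumerate_networks_nw(c("A", "B", "C", "D"), 0),
    netcoal:::enumerate_networks_nw(c("A", "B", "C", "D"), 1))
}

test_that("move selection follows the hierarchical scheme", {
  tree <- parseENewick("((A:1,B:1):1,C:1);")
  net <- parseENewick("((A:1,(B:0.5)#H1:0.5::0.3):1,(#H1:0.5::0.7,C:1):1);")
  cfg <- moveConfig(kappa = 0.3, kappa1 = 0.4, omega = 0.6, omega1 = 0.7)

  p_tree <- moveProbabilities(tree, cfg)
  expect_equal(sum(p_tree), 1)
  expect_identical(unname(p_tree[c("deleteReticulation", "changeInheritance",
                                   "moveHead", "flipReticulation")]),
                   c(0, 0, 0, 0))
  expect_equal(unname(p_tree["addReticulation"]), 0.3)      # absorbs kappa1
  expect_equal(unname(p_tree["changeLength"]), 0.7 * 0.6)   # absorbs omega1
  expect_equal(unname(p_tree["moveTail"]), 0.7 * 0.4)       # absorbs xi2, xi3

  p_net <- moveProbabilities(net, cfg)
  expect_equal(sum(p_net), 1)
  expect_equal(unname(p_net["addReticulation"]), 0.3 * 0.4)
  expect_equal(unname(p_net["deleteReticulation"]), 0.3 * 0.6)
  expect_equal(unname(p_net["changeInheritance"]), 0.7 * 0.6 * 0.3)

  # a tree never selects a reticulation-dependent move
  set.seed(3)
  kinds <- replicate(500, selectMove(tree, cfg))
  expect_true(all(kinds %in% c("changeLength", "moveTail", "addReticulation")))

  # kappa = 1 on a network: only the dimension-changing pair, at kappa1
  cfg1 <- moveConfig(kappa = 1, kappa1 = 0.4)
  kinds <- replicate(2000, selectMove(net, cfg1))
  expect_true(all(kinds %in% c("addReticulation", "deleteReticulation")))
  expect_lt(abs(mean(kinds == "addReticulation") - 0.4),
            3 * sqrt(0.4 * 0.6 / 2000))

  # kappa = 0, omega = 1: only the non-topology pair
  cfg2 <- moveConfig(kappa = 0, omega = 1)
  kinds <- replicate(500, selectMove(net, cfg2))
  expect_true(all(kinds %in% c("changeLength", "changeInheritance")))
})

test_that("window moves reflect correctly and keep the topology fixed", {
  net <- parseENewick("((A:1,(B:0.5)#H1:0.5::0.3):1,(#H1:0.5::0.7,C:1):1);")
  nw <- nwx(net)
  cfg <- moveConfig()
  cfg$addLengthRate <- 1
  key <- topologyKey(net)

  # lambda = 2.0, draw +0.3 -> 2.3
  i <- which(nw$edge[, 1] == nw$root)[1]
  nw$len[i] <- 2.0
  res <- netcoal:::propose_change_length(nw, cfg,
                                         list(edge = nw$edge[i, ], delta = 0.3))
  expect_equal(res$nw$len[i], 2.3)
  expect_identical(res$logH, 0); expect_identical(res$logJ, 0)
  # lambda = 0.1, draw -0.3 -> reflected to 0.2
  nw$len[i] <- 0.1
  res <- netcoal:::propose_change_length(nw, cfg,
                                         list(edge = nw$edge[i, ], delta = -0.3))
  expect_equal(res$nw$len[i], 0.2)
  expect_identical(netcoal:::topology_key_nw(res$nw), key)

  # gamma 0.5 + 0.2 -> 0.7; gamma 0.9 + 0.2 -> reflected to 0.9 at 1
  r <- netcoal:::nw_retic_nodes(nw)[1]
  ein <- which(nw$edge[, 2] == r)
  nw$gamma[ein] <- c(0.5, 0.5)
  res <- netcoal:::propose_change_inheritance(nw, cfg,
                                              list(node = r, delta = 0.2))
  expect_equal(sort(res$nw$gamma[ein]), c(0.3, 0.7))
  nw$gamma[ein] <- c(0.9, 0.1)
  res <- netcoal:::propose_change_inheritance(nw, cfg,
                                              list(node = r, delta = 0.2))
  expect_equal(res$nw$gamma[ein][1], 0.9)    # 1.1 reflects back to 0.9
  expect_identical(netcoal:::topology_key_nw(res$nw), key)
})

test_that("moves 1-5 carry zero Jacobian over random applications", {
  set.seed(41)
  cfg <- moveConfig(kappa = 0.3)
  cfg$addLengthRate <- 1
  pool <- move_pool()
  nonrj <- c("changeLength", "changeInheritance", "moveTail", "moveHead",
             "flipReticulation")
  n_ok <- 0L
  for (rep in 1:800) {
    nw <- randomize_nw(pool[[sample.int(length(pool), 1)]])
    kind <- sample(nonrj, 1)
    if (kind %in% c("changeInheritance", "moveHead", "flipReticulation") &&
        length(netcoal:::nw_retic_nodes(nw)) == 0L) next
    res <- netcoal:::propose_nw(nw, kind, cfg)
    if (!res$ok) next
    expect_identical(res$logJ, 0)
    n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 400L)
})

test_that("every move reverses exactly, with negated Hastings terms", {
  set.seed(42)
  cfg <- moveConfig(kappa = 0.3)
  cfg$addLengthRate <- 1
  pool <- move_pool()
  reverse_kind <- c(changeLength = "changeLength",
                    changeInheritance = "changeInheritance",
                    moveTail = "moveTail", moveHead = "moveHead",
                    flipReticulation = "flipReticulation",
                    addReticulation = "deleteReticulation",
                    deleteReticulation = "addReticulation")
  tried <- structure(integer(7), names = netcoal:::MOVE_KINDS)
  for (rep in 1:2000) {
    nw <- randomize_nw(pool[[sample.int(length(pool), 1)]])
    kind <- sample(netcoal:::MOVE_KINDS, 1)
    if (kind %in% c("changeInheritance", "moveHead", "flipReticulation",
                    "deleteReticulation") &&
        length(netcoal:::nw_retic_nodes(nw)) == 0L) next
    fw <- netcoal:::propose_nw(nw, kind, cfg)
    if (!fw$ok || !netcoal:::nw_is_valid(fw$nw)) next
    tried[kind] <- tried[kind] + 1L
    rv <- netcoal:::propose_nw(fw$nw, reverse_kind[kind], cfg,
                               choices = fw$reverse)
    expect_true(nw_identical(rv$nw, nw),
                info = sprintf("%s on %s", kind,
                               netcoal:::write_enewick_nw(nw)))
    expect_lt(abs((fw$logH + fw$logJ) + (rv$logH + rv$logJ)), 1e-9)
  }
  expect_true(all(tried > 100L))
})

test_that("structural contracts of individual moves hold", {
  net <- parseENewick("((A:1,(B:0.5)#H1:0.5::0.3):1,(#H1:0.5::0.7,C:1):1);")
  nw <- nwx(net)
  cfg <- moveConfig()
  cfg$addLengthRate <- 1

  # double flip restores the topology key
  elig <- netcoal:::flip_eligible(nw)
  f1 <- netcoal:::propose_nw(nw, "flipReticulation", cfg,
                             list(edge = nw$edge[elig[1], ], gamma = 0.4))
  if (netcoal:::nw_is_valid(f1$nw)) {
    f2 <- netcoal:::propose_nw(f1$nw, "flipReticulation", cfg, f1$reverse)
    expect_identical(netcoal:::topology_key_nw(f2$nw),
                     netcoal:::topology_key_nw(nw))
    # reticulation count unchanged by a flip
    expect_identical(length(netcoal:::nw_retic_nodes(f1$nw)), 1L)
  }

  # deleting the only reticulation yields a valid tree, lengths conserved
  del <- netcoal:::propose_nw(nw, "deleteReticulation", cfg)
  expect_true(netcoal:::nw_is_valid(del$nw))
  expect_identical(length(netcoal:::nw_retic_nodes(del$nw)), 0L)
  # suppressed nodes merge their incident branch lengths: the total drops
  # by exactly the deleted reticulation edge's length
  expect_equal(sum(del$nw$len), sum(nw$len) - del$reverse$len,
               tolerance = 1e-9)

  # move-tail onto its original position keeps the topology key
  te <- netcoal:::tail_eligible(nw)
  pair <- nw$edge[te[1], ]
  x <- pair[1]
  px <- which(nw$edge[, 2] == x)
  xc <- setdiff(which(nw$edge[, 1] == x), te[1])
  back <- c(nw$edge[px, 1], nw$edge[xc, 2])
  mt <- netcoal:::propose_nw(nw, "moveTail", cfg,
                             list(edge = pair, dest = back,
                                  destLen = nw$len[px] + nw$len[xc],
                                  h = nw$len[px]))
  expect_identical(netcoal:::topology_key_nw(mt$nw),
                   netcoal:::topology_key_nw(nw))

  # add on a tree then delete with the logged reverse restores the tree
  tree <- nwx(parseENewick("((A:1,B:1):1,C:1);"))
  ad <- netcoal:::propose_nw(tree, "addReticulation", cfg)
  if (netcoal:::nw_is_valid(ad$nw)) {
    bk <- netcoal:::propose_nw(ad$nw, "deleteReticulation", cfg, ad$reverse)
    expect_true(nw_identical(bk$nw, tree))
    expect_lt(abs((ad$logH + ad$logJ) + (bk$logH + bk$logJ)), 1e-9)
  }

  # add with both attachment points on one edge is invalid (cycle or
  # parallel pair), exactly as the prior expects
  E <- nrow(tree$edge)
  same <- netcoal:::propose_nw(tree, "addReticulation", cfg,
                               list(edge1 = tree$edge[1, ],
                                    edge2 = tree$edge[1, ], h1 = 0.7,
                                    h2 = 0.2, len = 0.5, gamma = 0.5))
  expect_gt(nrow(validateNetwork(same$nw)), 0L)
  expect_true(any(validateNetwork(same$nw)$kind %in%
                    c("cycle", "parallel-edge")))
})

test_that("prior-only chains reach every topology on three taxa", {
  cfg <- runConfig(iterations = 5e4, burnin = 0, thin = 5, seed = 19,
                   prior = priorConfig(nu = 1.5, tNmMode = "auto"),
                   moves = moveConfig(kappa = 0.35, maxReticulations = 1),
                   species = c("A", "B", "C"))
  ch <- runChain(NULL, cfg)
  seen <- unique(ch@records$key)
  want <- vapply(c(netcoal:::enumerate_networks_nw(c("A", "B", "C"), 0),
                   netcoal:::enumerate_networks_nw(c("A", "B", "C"), 1)),
                 netcoal:::topology_key_nw, "")
  expect_true(all(want %in% seen))
})
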