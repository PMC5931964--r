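# Newman-Girvan Q, jackknife error and module connectivity tests.

test_that("Q matches hand-computed and degenerate cases", {
  net <- make_net(rbind(clique_edges(c("a", "b", "c")),
                        clique_edges(c("d", "e", "f")),
                        c("a", "d")))
  all_one <- stats::setNames(rep(1L, 6L), nodeLabels(net))
  expect_equal(modularityQ(net, all_one), 0)
  tri <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                         c("a", "b", "c", "d", "e", "f"))
  expect_equal(modularityQ(net, tri), 6 / 7 - 1 / 2)
  expect_equal(round(modularityQ(net, tri), 3L), 0.357)

  single_edge <- make_net(rbind(c("a", "b")))
  expect_equal(modularityQ(net = single_edge,
                           stats::setNames(c(1L, 2L), c("a", "b"))), -0.5)

  expect_error(modularityQ(net, tri[-1L]), class = "membershipError")
})

test_that("Q agrees with the independent igraph implementation", {
  set.seed(31)
  for (i in 1:15) {
    net <- random_connected_net(sample(5:10, 1L), p = 0.4)
    part <- bestPartition(walktrapTree(net), net)
    mem <- moduleMembership(part)
    expect_equal(qValue(part),
                 igraph::modularity(asIgraph(net),
                                    mem[nodeLabels(net)]))
    # random partitions too, not just detected ones
    rnd <- stats::setNames(sample(1:3, nodeCount(net), replace = TRUE),
                           nodeLabels(net))
    expect_equal(modularityQ(net, rnd),
                 igraph::modularity(asIgraph(net), rnd[nodeLabels(net)]))
  }
})

test_that("jackknife SE vanishes on symmetric cases and matches the oracle", {
  # 4-cycle, alternating (diagonal) modules: the rotation that swaps the
  # modules maps every edge onto another, so all leave-one-out Q are equal
  c4 <- cycle_net(4L)
  alt <- stats::setNames(c(1L, 2L, 1L, 2L), nodeLabels(c4))
  expect_equal(jackknifeQSE(c4, alt), 0)
  # single module on an edge-transitive cycle
  c6 <- cycle_net(6L)
  one <- stats::setNames(rep(1L, 6L), nodeLabels(c6))
  expect_equal(jackknifeQSE(c6, one), 0)

  # asymmetric case: matches an independent leave-one-out loop
  net <- make_net(rbind(clique_edges(c("a", "b", "c")),
                        clique_edges(c("d", "e", "f")),
                        c("a", "d")))
  tri <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                         c("a", "b", "c", "d", "e", "f"))
  se <- jackknifeQSE(net, tri)
  expect_gt(se, 0)
  expect_equal(se, brute_jackknife(net, tri))

  set.seed(37)
  for (i in 1:5) {
    rnet <- random_connected_net(7L, p = 0.5)
    part <- bestPartition(walktrapTree(rnet), rnet)
    expect_equal(jackknifeQSE(rnet, part),
                 brute_jackknife(rnet, moduleMembership(part)))
  }

  expect_error(jackknifeQSE(make_net(rbind(c("a", "b"))),
                            stats::setNames(c(1L, 1L), c("a", "b"))),
               class = "tooFewEdgesError")
})

test_that("scorePartition fills q and its jackknife error", {
  net <- two_cliques(5L)
  part <- scorePartition(net, bestPartition(walktrapTree(net), net))
  expect_false(is.na(qStandardError(part)))
  expect_equal(qStandardError(part),
               brute_jackknife(net, moduleMembership(part)))
})

test_that("module test separates a clique module with exact p", {
  net <- two_cliques(5L)
  part <- bestPartition(walktrapTree(net), net)
  tt <- moduleTest(net, part, 1L)
  expect_equal(sort(tt@internal), rep(4, 5))
  expect_equal(sort(tt@external), c(0, 0, 0, 0, 1))
  expect_equal(tt@pValue, 1 / 252)
  expect_equal(round(tt@pValue, 3L), 0.004)
  expect_true(tt@reliable)
  # both clique modules significant
  tt2 <- moduleTest(net, part, 2L)
  expect_lt(tt2@pValue, 0.05)
})

test_that("exact enumeration matches wilcox.test on tie-free samples", {
  set.seed(43)
  for (i in 1:10) {
    x <- sample(seq(1, 40, by = 2), 5L)       # odd values
    y <- sample(seq(2, 40, by = 2), 6L)       # even values: no cross ties
    p_ref <- stats::wilcox.test(x, y, alternative = "greater",
                                exact = TRUE)$p.value
    p_enum <- anatnet:::.exactRankSumP(x, y)
    expect_equal(p_enum, p_ref)
  }
})

test_that("a module pointing the wrong way is not significant", {
  # half of a complete graph on 8 nodes: internal 3 each, external 4 each
  net <- make_net(clique_edges(letters[1:8]))
  mem <- stats::setNames(rep(c(1L, 2L), each = 4L), letters[1:8])
  tt <- moduleTest(net, mem, 1L)
  expect_equal(tt@internal, rep(3, 4))
  expect_equal(tt@external, rep(4, 4))
  expect_gte(tt@pValue, 0.5)
})

test_that("small modules are flagged unreliable but still tested", {
  net <- triangle_pendant()
  mem <- stats::setNames(c(1L, 1L, 1L, 2L), c("a", "b", "c", "d"))
  tt <- moduleTest(net, mem, 2L)
  expect_false(tt@reliable)
  expect_true(tt@pValue > 0 && tt@pValue <= 1)
  expect_error(moduleTest(net, mem, 9L), class = "unknownModuleError")
})

test_that("the module table covers every module and can Holm-adjust", {
  net <- two_cliques(4L)
  part <- bestPartition(walktrapTree(net), net)
  tab <- moduleTestTable(net, part)
  expect_equal(nrow(tab), length(unique(moduleMembership(part))))
  expect_true(all(c("module", "size", "members", "classes",
                    "internal_links", "external_links", "W", "p",
                    "reliable") %in% names(tab)))
  tab2 <- moduleTestTable(net, part, adjust = "holm")
  expect_true(all(tab2$p_adj >= tab2$p))
})

test_that("planted clique modules test significant at alpha 0.05", {
  for (r in c(4L, 5L)) {
    net <- two_cliques(r)
    part <- bestPartition(walktrapTree(net), net)
    tab <- moduleTestTable(net, part)
    expect_true(all(tab$p < 0.05))
  }
})
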