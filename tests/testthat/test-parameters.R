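# The six descriptors N, K, D, C, L, H.

test_that("degree sequence sums to twice the edge count", {
  expect_equal(unname(degreeSequence(make_net(clique_edges(c("a", "b", "c"))))),
               c(2L, 2L, 2L))
  expect_equal(sort(unname(degreeSequence(star_net(3L))), decreasing = TRUE),
               c(3L, 1L, 1L, 1L))
  empty <- anatomicalNetwork(stats::setNames(rep("bone", 4), letters[1:4]))
  expect_equal(unname(degreeSequence(empty)), rep(0L, 4L))
  for (n in c(5L, 9L)) {
    net <- random_connected_net(n)
    expect_equal(sum(degreeSequence(net)), 2L * edgeCount(net))
  }
})

test_that("density is the realised fraction of possible links", {
  expect_equal(networkDensity(make_net(clique_edges(letters[1:4]))), 1)
  path3 <- make_net(rbind(c("a", "b"), c("b", "c")))
  expect_equal(round(networkDensity(path3), 3L), 0.667)
  single <- anatomicalNetwork(c(a = "bone"))
  expect_error(networkDensity(single), class = "tooFewNodesError")
  # D reconstructs K exactly
  net <- random_connected_net(10L)
  n <- nodeCount(net)
  expect_equal(networkDensity(net) * n * (n - 1) / 2, edgeCount(net))
})

test_that("clustering handles low-degree nodes per the chosen mode", {
  expect_equal(meanClustering(make_net(clique_edges(letters[1:4]))), 1)
  expect_equal(meanClustering(star_net(3L)), 0)
  expect_equal(meanClustering(star_net(3L), "zero"), 0)
  tp <- triangle_pendant()
  expect_equal(round(meanClustering(tp, "exclude"), 3L), 0.778)
  expect_equal(meanClustering(tp, "exclude"), (1 / 3 + 1 + 1) / 3)
  expect_equal(meanClustering(tp, "zero"), 7 / 12)
  # no qualifying node at all
  single_edge <- make_net(rbind(c("a", "b")))
  expect_equal(meanClustering(single_edge, "exclude"), 0)
})

test_that("path length averages geodesics and rejects disconnection", {
  expect_equal(meanPathLength(make_net(clique_edges(letters[1:4]))), 1)
  expect_equal(round(meanPathLength(make_net(rbind(c("a", "b"),
                                                   c("b", "c")))), 3L),
               1.333)
  expect_equal(meanPathLength(cycle_net(4L)), 8 / 6)
  disc <- make_net(rbind(c("a", "b"), c("c", "d")))
  err <- tryCatch(meanPathLength(disc), error = identity)
  expect_s3_class(err, "disconnectedError")
  expect_match(conditionMessage(err), "2, 2")
  expect_warning(L <- meanPathLength(disc, largestComponent = TRUE),
                 "largest component")
  expect_equal(L, 1)
})

test_that("heterogeneity is the cv of degrees, zero iff regular", {
  expect_equal(degreeHeterogeneity(cycle_net(5L)), 0)
  expect_equal(round(degreeHeterogeneity(star_net(3L)), 3L), 0.667)
  two_edges <- make_net(rbind(c("a", "b"), c("c", "d")))
  expect_equal(degreeHeterogeneity(two_edges), 0)
  # population sd differs by the sqrt((n-1)/n) factor
  st <- star_net(3L)
  expect_equal(degreeHeterogeneity(st, "population"),
               degreeHeterogeneity(st, "sample") * sqrt(3 / 4))
  iso <- anatomicalNetwork(c(a = "bone", b = "bone"))
  expect_error(degreeHeterogeneity(iso), class = "isolatedNetworkError")
  # invariant under relabelling
  net <- random_connected_net(8L)
  relab <- anatomicalNetwork(
    data.frame(label = rev(toupper(nodeLabels(net))),
               class = rev(unname(nodeClasses(net)))),
    toupper(as.matrix(edgeTable(net))))
  expect_equal(degreeHeterogeneity(relab), degreeHeterogeneity(net))
})

test_that("the parameter bundle matches per-operation values", {
  p <- networkParameters(triangle_pendant())
  expect_equal(p@N, 4)
  expect_equal(p@K, 4)
  expect_equal(round(p@D, 3L), 0.667)
  expect_equal(round(p@C, 3L), 0.778)
  expect_equal(round(p@L, 3L), 1.333)
  expect_equal(round(p@H, 3L), 0.408)
  expect_equal(p@H, stats::sd(c(3, 2, 2, 1)) / 2)

  k5 <- networkParameters(make_net(clique_edges(letters[1:5])))
  expect_equal(parameterVector(k5),
               c(N = 5, K = 10, D = 1, C = 1, L = 1, H = 0))
})

test_that("C and L agree with brute-force oracles on random graphs", {
  set.seed(7)
  for (i in 1:40) {
    net <- random_connected_net(sample(4:12, 1L), p = stats::runif(1, 0.25, 0.7))
    expect_equal(meanClustering(net, "exclude"),
                 brute_mean_clustering(net, "exclude"))
    expect_equal(meanClustering(net, "zero"),
                 brute_mean_clustering(net, "zero"))
    expect_equal(meanPathLength(net), brute_mean_path_length(net))
  }
})

test_that("adding an edge never decreases D nor increases L", {
  set.seed(11)
  for (i in 1:10) {
    net <- random_connected_net(7L, p = 0.4)
    M <- adj_matrix(net)
    off <- which(upper.tri(M) & M == 0L, arr.ind = TRUE)
    if (nrow(off) == 0L) next
    pick <- off[sample.int(nrow(off), 1L), ]
    labs <- nodeLabels(net)
    bigger <- make_net(rbind(as.matrix(edgeTable(net)),
                             c(labs[pick[1L]], labs[pick[2L]])),
                       labels = labs)
    expect_gte(networkDensity(bigger), networkDensity(net))
    expect_lte(meanPathLength(bigger), meanPathLength(net))
  }
})
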