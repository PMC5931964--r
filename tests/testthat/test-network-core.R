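# Construction, loading, validation and slicing of anatomical networks.

write_adjacency <- function(M, path) {
  df <- data.frame(label = rownames(M), M, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

write_classes <- function(labels, classes, path) {
  utils::write.csv(data.frame(label = labels, class = classes), path,
                   row.names = FALSE, quote = FALSE)
}

test_that("a labelled adjacency matrix loads into the encoded network", {
  M <- matrix(0L, 3L, 3L, dimnames = list(c("a", "b", "c"),
                                          c("a", "b", "c")))
  M["a", "b"] <- M["b", "a"] <- 1L
  M["b", "c"] <- M["c", "b"] <- 1L
  adj <- withr::local_tempfile(fileext = ".csv")
  cls <- withr::local_tempfile(fileext = ".csv")
  write_adjacency(M, adj)
  write_classes(c("a", "b", "c"), c("bone", "bone", "muscle"), cls)
  net <- readAnatomicalNetwork(adj, cls, name = "toy")
  expect_s4_class(net, "AnatomicalNetwork")
  expect_equal(nodeCount(net), 3L)
  expect_equal(edgeCount(net), 2L)
  expect_equal(unname(nodeClasses(net)[c("a", "c")]), c("bone", "muscle"))
})

test_that("edge count equals the above-diagonal ones of a large matrix", {
  # 94 units, 193 contacts: the scale of a hominid forelimb matrix
  set.seed(41)
  labs <- sprintf("u%03d", 1:94)
  M <- matrix(0L, 94L, 94L, dimnames = list(labs, labs))
  up <- which(upper.tri(M))
  on <- sample(up, 193L)
  M[on] <- 1L
  M <- M + t(M)
  adj <- withr::local_tempfile(fileext = ".csv")
  cls <- withr::local_tempfile(fileext = ".csv")
  write_adjacency(M, adj)
  write_classes(labs, rep(c("bone", "muscle"), length.out = 94L), cls)
  net <- readAnatomicalNetwork(adj, cls)
  expect_equal(nodeCount(net), 94L)
  expect_equal(edgeCount(net), 193L)
  expect_equal(round(networkDensity(net), 3L), 0.044)
})

test_that("each coding violation raises its own typed error", {
  labs <- c("a", "b", "c")
  base <- matrix(0L, 3L, 3L, dimnames = list(labs, labs))
  base["a", "b"] <- base["b", "a"] <- 1L
  cls <- withr::local_tempfile(fileext = ".csv")
  write_classes(labs, rep("bone", 3L), cls)
  wr <- function(M) {
    f <- tempfile(fileext = ".csv")
    write_adjacency(M, f)
    f
  }

  expect_error(readAnatomicalNetwork(wr(base[, 1:2]), cls),
               class = "nonsquareError")

  asym <- base
  asym["a", "c"] <- 1L  # A[a,c]=1 but A[c,a]=0
  expect_error(readAnatomicalNetwork(wr(asym), cls),
               class = "asymmetryError")
  # opt-in symmetrization takes max(A, t(A))
  net <- readAnatomicalNetwork(wr(asym), cls, symmetrize = TRUE)
  expect_equal(edgeCount(net), 2L)

  diagM <- base
  diagM["b", "b"] <- 1L
  expect_error(readAnatomicalNetwork(wr(diagM), cls),
               class = "diagonalError")

  badval <- base
  badval["a", "c"] <- 2L
  badval["c", "a"] <- 2L
  expect_error(readAnatomicalNetwork(wr(badval), cls),
               class = "invalidEntryError")

  cls2 <- withr::local_tempfile(fileext = ".csv")
  write_classes(c("a", "b"), c("bone", "bone"), cls2)
  expect_error(readAnatomicalNetwork(wr(base), cls2),
               class = "missingClassError")

  mism <- base
  colnames(mism) <- c("a", "b", "x")
  expect_error(readAnatomicalNetwork(wr(mism), cls),
               class = "labelMismatchError")
})

test_that("validateNetwork reports violations without throwing", {
  tri <- make_net(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_length(validateNetwork(tri), 0L)

  ghost <- new("AnatomicalNetwork", name = "bad",
               nodes = data.frame(label = c("a", "b"),
                                  class = c("bone", "bone")),
               edges = rbind(c("a", "x")))
  v <- validateNetwork(ghost)
  expect_length(v, 1L)
  expect_match(v, "'x'")

  dup <- new("AnatomicalNetwork", name = "bad",
             nodes = data.frame(label = c("a", "a"),
                                class = c("bone", "bone")),
             edges = matrix(character(0), ncol = 2L))
  v <- validateNetwork(dup)
  expect_length(v, 1L)
  expect_match(v, "'a'")

  wrongcls <- new("AnatomicalNetwork", name = "bad",
                  nodes = data.frame(label = "a", class = "tendon"),
                  edges = matrix(character(0), ncol = 2L))
  expect_match(validateNetwork(wrongcls), "tendon")
})

test_that("round-trip through CSV reproduces the network exactly", {
  net <- generateLimbNetwork(presetLimbSpec("pan_like_forelimb"))
  adj <- withr::local_tempfile(fileext = ".csv")
  cls <- withr::local_tempfile(fileext = ".csv")
  writeAnatomicalNetwork(net, adj, cls)
  back <- readAnatomicalNetwork(adj, cls, name = networkName(net))
  expect_setequal(nodeLabels(back), nodeLabels(net))
  expect_equal(nodeClasses(back)[nodeLabels(net)], nodeClasses(net))
  expect_equal(back@edges, net@edges)
})

test_that("class slicing gives induced subgraphs with the expected algebra", {
  net <- make_net(rbind(c("femur", "tibia"), c("m_quad", "femur"),
                        c("m_quad", "tibia")),
                  labels = c("femur", "tibia", "m_quad"),
                  classes = c("bone", "bone", "muscle"))
  skel <- subNetwork(net, c("bone", "cartilage"))
  expect_equal(nodeCount(skel), 2L)
  expect_equal(edgeCount(skel), 1L)
  musc <- subNetwork(net, "muscle")
  expect_equal(nodeCount(musc), 1L)
  expect_equal(edgeCount(musc), 0L)
  full <- subNetwork(net, c("bone", "cartilage", "muscle"))
  expect_equal(full@edges, net@edges)
  expect_equal(full@nodes, net@nodes)
  expect_error(subNetwork(net, character(0)), class = "emptyClassSetError")

  # idempotence and intersection-commutativity
  expect_equal(subNetwork(skel, c("bone", "cartilage"))@edges, skel@edges)

  # skeletal + muscular + bone-muscle links partition the full edge set
  cls <- nodeClasses(net)
  e <- edgeTable(net)
  cross <- sum((cls[e$from] == "muscle") != (cls[e$to] == "muscle"))
  expect_equal(edgeCount(skel) + edgeCount(musc) + cross, edgeCount(net))
})

test_that("edge partition identity holds on generated limb networks", {
  net <- generateLimbNetwork(presetLimbSpec("homo_like_hindlimb"))
  skel <- subNetwork(net, c("bone", "cartilage"))
  musc <- subNetwork(net, "muscle")
  cls <- nodeClasses(net)
  e <- edgeTable(net)
  cross <- sum((cls[e$from] == "muscle") != (cls[e$to] == "muscle"))
  expect_equal(edgeCount(skel) + edgeCount(musc) + cross, edgeCount(net))
})

test_that("specimen consensus requires a strict majority", {
  expect_true(consensusPresence(c(rep(TRUE, 20), rep(FALSE, 18))))
  expect_false(consensusPresence(c(rep(TRUE, 19), rep(FALSE, 19))))
  expect_true(consensusPresence(c(rep(TRUE, 6), rep(FALSE, 5))))
  expect_error(consensusPresence(logical(0)),
               class = "emptyObservationsError")
})

test_that("GraphML and edge-list exports are written and readable", {
  net <- make_net(rbind(c("a", "b"), c("b", "c")))
  gml <- withr::local_tempfile(fileext = ".graphml")
  exportGraphML(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 3L)
  expect_equal(igraph::gsize(g), 2L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  exportEdgeList(net, tsv)
  el <- utils::read.delim(tsv)
  expect_equal(nrow(el), 2L)
})
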