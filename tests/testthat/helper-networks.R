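# Small network builders used across the suite.

make_net <- function(edges, labels = NULL, classes = NULL, name = "net") {
  if (is.null(labels))
    labels <- sort(unique(c(edges)))
  if (is.null(classes))
    classes <- rep("bone", length(labels))
  anatomicalNetwork(data.frame(label = labels, class = classes,
                               stringsAsFactors = FALSE),
                    edges, name = name)
}

clique_edges <- function(labels) t(utils::combn(labels, 2L))

# two r-cliques joined by a single bridge edge a1--b1
two_cliques <- function(r) {
  a <- sprintf("a%d", seq_len(r))
  b <- sprintf("b%d", seq_len(r))
  make_net(rbind(clique_edges(a), clique_edges(b), c("a1", "b1")),
           name = sprintf("two_%dcliques", r))
}

cycle_net <- function(n) {
  labs <- sprintf("v%02d", seq_len(n))
  make_net(cbind(labs, labs[c(2:n, 1L)]), name = sprintf("cycle%d", n))
}

star_net <- function(leaves) {
  labs <- sprintf("l%d", seq_len(leaves))
  make_net(cbind("hub", labs), name = "star")
}

triangle_pendant <- function() {
  make_net(rbind(c("a", "b"), c("b", "c"), c("a", "c"), c("a", "d")),
           name = "triangle_pendant")
}

# adjacency matrix of a network, in node order
adj_matrix <- function(net) {
  labs <- nodeLabels(net)
  M <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  e <- as.matrix(edgeTable(net))
  if (nrow(e)) {
    M[e] <- 1L
    M[e[, c(2L, 1L), drop = FALSE]] <- 1L
  }
  M
}

# Erdos-Renyi graph conditioned on connectivity, base-R only
random_connected_net <- function(n, p = 0.4) {
  labs <- sprintf("n%02d", seq_len(n))
  repeat {
    M <- matrix(0L, n, n)
    up <- which(upper.tri(M))
    M[up] <- as.integer(stats::runif(length(up)) < p)
    M <- M + t(M)
    # BFS connectivity check
    seen <- logical(n); seen[1L] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(M[v, ] > 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (all(seen) && sum(M) > 0) break
  }
  idx <- which(upper.tri(M) & M == 1L, arr.ind = TRUE)
  make_net(cbind(labs[idx[, 1L]], labs[idx[, 2L]]), labels = labs,
           name = "random")
}
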