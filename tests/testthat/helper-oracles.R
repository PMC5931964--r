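# Independent brute-force oracles, deliberately naive implementations
# that share no code with the package internals.

# local clustering by explicit neighbour-pair enumeration
brute_mean_clustering <- function(net, mode = c("exclude", "zero")) {
  mode <- match.arg(mode)
  M <- adj_matrix(net)
  n <- nrow(M)
  ci <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- which(M[i, ] == 1L)
    d <- length(nb)
    if (d < 2L) next
    links <- 0L
    for (a in seq_len(d - 1L)) for (b in (a + 1L):d)
      if (M[nb[a], nb[b]] == 1L) links <- links + 1L
    ci[i] <- links / (d * (d - 1) / 2)
  }
  if (mode == "zero") ci[is.na(ci)] <- 0
  vals <- ci[!is.na(ci)]
  if (!length(vals)) 0 else mean(vals)
}

# all-pairs shortest paths by repeated BFS
brute_mean_path_length <- function(net) {
  M <- adj_matrix(net)
  n <- nrow(M)
  total <- 0
  npairs <- 0L
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in which(M[v, ] == 1L)) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    later <- seq_len(n) > s
    total <- total + sum(dist[later])
    npairs <- npairs + sum(later)
  }
  total / npairs
}

# Newman-Girvan Q straight from the definition, membership = named vector
brute_q <- function(net, mem) {
  e <- edgeTable(net)
  K <- nrow(e)
  mods <- unique(mem)
  q <- 0
  for (s in mods) {
    ess <- sum(mem[e$from] == s & mem[e$to] == s) / K
    ends <- (sum(mem[e$from] == s) + sum(mem[e$to] == s)) / (2 * K)
    q <- q + ess - ends^2
  }
  q
}

# leave-one-edge-out jackknife with the definition formula
brute_jackknife <- function(net, mem) {
  e <- edgeTable(net)
  K <- nrow(e)
  qi <- vapply(seq_len(K), function(i) {
    sub <- make_net(as.matrix(e[-i, ]), labels = nodeLabels(net),
                    classes = unname(nodeClasses(net)))
    brute_q(sub, mem)
  }, numeric(1))
  sqrt((K - 1) / K * sum((qi - mean(qi))^2))
}

# all set partitions of n elements as restricted-growth strings, memoised
.partition_cache <- new.env(parent = emptyenv())
all_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  rgs <- matrix(1L, 1L, 1L)
  mx <- 1L
  for (k in seq_len(n - 1L)) {
    reps <- mx + 1L
    rows <- rep(seq_len(nrow(rgs)), reps)
    newcol <- unlist(lapply(reps, seq_len))
    rgs <- cbind(rgs[rows, , drop = FALSE], newcol)
    mx <- pmax(mx[rows], newcol)
  }
  dimnames(rgs) <- NULL
  .partition_cache[[key]] <- rgs
  rgs
}

# exhaustive maximum modularity over every partition of the node set
exhaustive_max_q <- function(net) {
  labs <- nodeLabels(net)
  n <- length(labs)
  M <- all_partitions(n)
  e <- edgeTable(net)
  K <- nrow(e)
  ei <- match(e$from, labs)
  ej <- match(e$to, labs)
  intra <- rep(0L, nrow(M))
  for (k in seq_len(K))
    intra <- intra + (M[, ei[k]] == M[, ej[k]])
  deg <- as.numeric(degreeSequence(net))
  pairsum <- rep(0, nrow(M))
  for (i in seq_len(n)) for (j in seq_len(n))
    pairsum <- pairsum + deg[i] * deg[j] * (M[, i] == M[, j])
  q <- intra / K - pairsum / (4 * K^2)
  max(q)
}
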