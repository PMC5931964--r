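# Short-random-walk agglomerative community detection.
#
# Implemented from the published random-walk method rather than wrapped:
# t-step transition probabilities of the degree-normalised walk give each
# node a probability profile; the distance between two communities is the
# degree-weighted Euclidean distance between their mean profiles; at each
# step the adjacent pair of communities whose merger least increases the
# mean squared node-to-community distance (Ward criterion
# dSigma = |C1||C2| / (|C1|+|C2|) / N * r^2) is merged.  Node labels are
# sorted into C-locale order first, and cost ties are broken on the
# lexicographically smallest (min member label, max member label) pair, so
# the merge sequence is deterministic and independent of input node order.

#' Grow the random-walk merge tree of a network
#'
#' Runs the agglomeration described above with walks of `steps` steps
#' (default 3, the length that makes short walks concentrate within
#' modules at limb-network scale) and records the full merge history.
#'
#' @param net a connected [AnatomicalNetwork-class] with at least 2 nodes.
#' @param steps positive integer walk length (t).
#' @return a [WalktrapTree-class] with exactly N - 1 merges.
#' @seealso [bestPartition()], [cutTree()]
#' @export
setMethod("walktrapTree", "AnatomicalNetwork", function(net, steps = 3L) {
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L)
    .anStop("invalidStepsError", "'steps' must be a positive integer")
  n <- nodeCount(net)
  if (n < 2L)
    .anStop("tooFewNodesError", "module detection needs at least 2 nodes")
  .connectedOrStop(asIgraph(net), sprintf("network '%s'", networkName(net)))

  labs <- .csort(nodeLabels(net))
  A <- matrix(0, n, n, dimnames = list(labs, labs))
  e <- net@edges
  A[cbind(e[, 1L], e[, 2L])] <- 1
  A[cbind(e[, 2L], e[, 1L])] <- 1
  deg <- rowSums(A)
  P <- A / deg
  Pt <- P
  if (steps > 1L) for (s in seq_len(steps - 1L)) Pt <- Pt %*% P

  # community state, ids 1..n for singletons, n+step for merged ones
  nc <- 2L * n - 1L
  members <- vector("list", nc)
  members[seq_len(n)] <- as.list(seq_len(n))
  profile <- matrix(NA_real_, nc, n)
  profile[seq_len(n), ] <- Pt
  repLab <- c(labs, rep(NA_character_, n - 1L))
  nbrs <- vector("list", nc)
  for (i in seq_len(n)) nbrs[[i]] <- which(A[i, ] > 0)
  alive <- c(rep(TRUE, n), rep(FALSE, n - 1L))

  merges <- matrix(0L, n - 1L, 2L)
  dsRec <- numeric(n - 1L)

  dsigma <- function(a, b) {
    sa <- length(members[[a]]); sb <- length(members[[b]])
    r2 <- sum((profile[a, ] - profile[b, ])^2 / deg)
    (sa * sb / (sa + sb)) / n * r2
  }

  for (step in seq_len(n - 1L)) {
    ids <- which(alive)
    pa <- integer(0); pb <- integer(0)
    for (a in ids) {
      bs <- nbrs[[a]]
      bs <- bs[bs > a]
      if (length(bs)) { pa <- c(pa, rep(a, length(bs))); pb <- c(pb, bs) }
    }
    ds <- vapply(seq_along(pa), function(k) dsigma(pa[k], pb[k]),
                 numeric(1))
    lo <- ifelse(.corder2(repLab[pa], repLab[pb]), repLab[pa], repLab[pb])
    hi <- ifelse(.corder2(repLab[pa], repLab[pb]), repLab[pb], repLab[pa])
    pick <- .corder(ds, lo, hi)[1L]
    a <- pa[pick]; b <- pb[pick]
    newId <- n + step
    members[[newId]] <- c(members[[a]], members[[b]])
    profile[newId, ] <- colMeans(Pt[members[[newId]], , drop = FALSE])
    lr <- c(repLab[a], repLab[b])
    repLab[newId] <- lr[.corder(lr)[1L]]
    newNb <- setdiff(union(nbrs[[a]], nbrs[[b]]), c(a, b))
    nbrs[[newId]] <- newNb
    for (x in newNb)
      nbrs[[x]] <- unique(c(setdiff(nbrs[[x]], c(a, b)), newId))
    alive[a] <- FALSE; alive[b] <- FALSE; alive[newId] <- TRUE
    merges[step, ] <- c(a, b)
    dsRec[step] <- ds[pick]
  }

  new("WalktrapTree", labels = labs, merges = merges, deltaSigma = dsRec,
      steps = steps, networkName = networkName(net))
})

setMethod("show", "WalktrapTree", function(object) {
  cat(sprintf(
    "WalktrapTree on '%s': %d nodes, %d merges, walk length %d\n",
    object@networkName, length(object@labels), nrow(object@merges),
    object@steps))
})

#' Cut a merge tree into a partition
#'
#' Replays the first `nMerges` merges and returns the resulting node ->
#' module assignment.  `nMerges = 0` gives all-singleton modules;
#' `nMerges = N - 1` a single module.  Module ids are renumbered to
#' contiguous integers by first appearance in canonical label order.
#'
#' @param tree a [WalktrapTree-class].
#' @param nMerges number of merges to apply (0 to N-1).
#' @return named integer vector: node label -> module id.
#' @export
cutTree <- function(tree, nMerges) {
  n <- length(tree@labels)
  nMerges <- as.integer(nMerges)
  if (nMerges < 0L || nMerges > n - 1L)
    .anStop("invalidCutError", "'nMerges' must lie in [0, %d]", n - 1L)
  comm <- seq_len(n)
  if (nMerges > 0L) {
    map <- seq_len(2L * n - 1L)
    for (s in seq_len(nMerges)) {
      a <- tree@merges[s, 1L]; b <- tree@merges[s, 2L]
      map[map == map[a]] <- n + s
      map[map == map[b]] <- n + s
    }
    comm <- map[seq_len(n)]
  }
  ids <- match(comm, unique(comm))
  stats::setNames(as.integer(ids), tree@labels)
}

#' Select the modularity-optimal level of a merge tree
#'
#' Evaluates Newman-Girvan Q at every level of the merge tree (from N
#' singletons to one community) and returns the partition of maximal Q.
#' Exact Q ties are broken toward fewer modules.
#'
#' @param tree a [WalktrapTree-class] grown on `net`.
#' @param net the same [AnatomicalNetwork-class] the tree was grown on.
#' @return a [ModulePartition-class] with its `q` filled in (`qSE` is
#'   `NA` until [jackknifeQSE()] is applied).
#' @export
setMethod("bestPartition", c("WalktrapTree", "AnatomicalNetwork"),
function(tree, net) {
  if (!setequal(tree@labels, nodeLabels(net)))
    .anStop("treeMismatchError",
            "tree and network node sets differ")
  n <- length(tree@labels)
  bestQ <- -Inf; bestM <- 0L
  for (m in 0:(n - 1L)) {
    q <- modularityQ(net, cutTree(tree, m))
    if (q > bestQ + 1e-12) {
      bestQ <- q; bestM <- m
    } else if (abs(q - bestQ) <= 1e-12 && m > bestM) {
      # equal Q, later level = fewer modules
      bestQ <- q; bestM <- m
    }
  }
  mem <- cutTree(tree, bestM)
  new("ModulePartition", membership = mem, q = bestQ, qSE = NA_real_,
      networkName = networkName(net))
})

#' @rdname accessors
#' @export
setMethod("moduleMembership", "ModulePartition", function(x) x@membership)

#' @rdname accessors
#' @export
setMethod("qValue", "ModulePartition", function(x) x@q)

#' @rdname accessors
#' @export
setMethod("qStandardError", "ModulePartition", function(x) x@qSE)

#' @rdname accessors
#' @export
setMethod("networkName", "ModulePartition", function(x) x@networkName)

setMethod("show", "ModulePartition", function(object) {
  k <- length(unique(object@membership))
  se <- if (is.na(object@qSE)) "" else sprintf(" +/- %.4f", object@qSE)
  cat(sprintf("ModulePartition of '%s': %d modules, Q = %.4f%s\n",
              object@networkName, k, object@q, se))
})
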