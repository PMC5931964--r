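# Newman-Girvan modularity, its jackknife error, and per-module
# internal-vs-external connectivity tests.

.membershipOf <- function(x) {
  if (is(x, "ModulePartition")) x@membership else x
}

.checkMembership <- function(net, mem) {
  if (is.null(names(mem)))
    .anStop("membershipError", "membership must be a named vector")
  miss <- setdiff(nodeLabels(net), names(mem))
  if (length(miss))
    .anStop("membershipError", "no module assignment for node(s): %s",
            paste(utils::head(miss, 5L), collapse = ", "))
  mem[nodeLabels(net)]
}

# Q from index arrays; `mem` may use arbitrary ids.
.qFromIndices <- function(memA, memB, degByModule, K) {
  eIn <- sum(memA == memB) / K
  aS <- degByModule / (2 * K)
  eIn - sum(aS^2)
}

#' Newman-Girvan modularity Q
#'
#' `Q = sum_s (e_ss - a_s^2)`, where `e_ss` is the fraction of links with
#' both endpoints in module s and `a_s` the fraction of link endpoints in
#' s.  Q is close to 0 when within-module link density is no better than
#' chance, and approaches 1 for strongly modular networks; empirically,
#' strongly modular networks score between 0.3 and 0.7.
#'
#' @param net an [AnatomicalNetwork-class] with at least one link.
#' @param membership named vector (node label -> module id) or a
#'   [ModulePartition-class]; must cover every node.
#' @return Q in [-0.5, 1].
#' @examples
#' # two triangles joined by one bridge, partitioned into the triangles:
#' # Q = 6/7 - 2 (7/14)^2 = 0.357
#' @export
modularityQ <- function(net, membership) {
  mem <- .checkMembership(net, .membershipOf(membership))
  K <- edgeCount(net)
  if (K == 0L)
    .anStop("noEdgesError", "modularity is undefined for an edgeless network")
  e <- net@edges
  memA <- mem[e[, 1L]]
  memB <- mem[e[, 2L]]
  degByModule <- vapply(split(as.integer(degreeSequence(net)),
                              as.character(mem)), sum, numeric(1))
  .qFromIndices(memA, memB, degByModule, K)
}

#' Jackknife standard error of Q
#'
#' Treats every link as an independent observation: for each link i the
#' network minus that link is rescored with the \emph{same} partition,
#' giving leave-one-out values Q(i), and the error is
#' `sqrt((K-1)/K * sum_i (Q(i) - mean(Q(i)))^2)`.  The partition is held
#' fixed across deletions, so the error reflects the sensitivity of the
#' score, not of the detection.
#'
#' @param net an [AnatomicalNetwork-class] with at least two links.
#' @param membership as in [modularityQ()].
#' @return the jackknife standard error (0 when every link is equivalent
#'   under a symmetry that preserves the partition).
#' @export
jackknifeQSE <- function(net, membership) {
  mem <- .checkMembership(net, .membershipOf(membership))
  K <- edgeCount(net)
  if (K < 2L)
    .anStop("tooFewEdgesError",
            "jackknife needs at least 2 links (got %d)", K)
  e <- net@edges
  deg <- as.integer(degreeSequence(net))
  names(deg) <- nodeLabels(net)
  memChr <- as.character(mem)
  names(memChr) <- names(mem)
  qi <- vapply(seq_len(K), function(i) {
    ei <- e[-i, , drop = FALSE]
    degi <- deg
    degi[e[i, 1L]] <- degi[e[i, 1L]] - 1L
    degi[e[i, 2L]] <- degi[e[i, 2L]] - 1L
    degByModule <- vapply(split(degi, memChr[names(degi)]), sum,
                          numeric(1))
    .qFromIndices(mem[ei[, 1L]], mem[ei[, 2L]], degByModule, K - 1L)
  }, numeric(1))
  sqrt((K - 1) / K * sum((qi - mean(qi))^2))
}

#' Attach Q and its jackknife error to a partition
#'
#' Convenience wrapper returning the partition with `q` and `qSE` filled.
#'
#' @param net an [AnatomicalNetwork-class].
#' @param partition a [ModulePartition-class].
#' @return the updated [ModulePartition-class].
#' @export
scorePartition <- function(net, partition) {
  partition@q <- modularityQ(net, partition)
  partition@qSE <- jackknifeQSE(net, partition)
  partition
}

# Exact one-sided rank-sum p by permutation enumeration: P(rank sum of a
# random size-n subset of the pooled midranks >= observed).  Valid with
# within-sample ties; callers ensure there are no cross-sample ties.
.exactRankSumP <- function(internal, external) {
  n <- length(internal); m <- length(external)
  rk <- rank(c(internal, external))
  w <- sum(rk[seq_len(n)])
  cmb <- utils::combn(n + m, n)
  sums <- colSums(matrix(rk[cmb], nrow = n))
  mean(sums >= w - 1e-9)
}

#' Internal-vs-external connectivity test of one module
#'
#' For every node of the module, counts its links to same-module nodes
#' (internal) and to the rest of the network (external), then applies the
#' one-sided two-sample Wilcoxon rank-sum test of Ha: internal > external.
#' When both samples have at most 10 observations and no value occurs in
#' both samples, the p-value is computed exactly by enumerating all rank
#' assignments (correct in the presence of within-sample ties); otherwise
#' the normal approximation with tie and continuity corrections is used.
#' Modules with fewer than 4 nodes are flagged `reliable = FALSE`: the
#' test cannot reach conventional significance at such sizes.  The
#' significance threshold (alpha = 0.05) is a reporting annotation, not a
#' filter.
#'
#' @param net an [AnatomicalNetwork-class].
#' @param membership as in [modularityQ()].
#' @param moduleId id of the module to test.
#' @return a [ModuleTest-class].
#' @export
moduleTest <- function(net, membership, moduleId) {
  mem <- .checkMembership(net, .membershipOf(membership))
  moduleId <- as.integer(moduleId)
  members <- names(mem)[mem == moduleId]
  if (length(members) == 0L)
    .anStop("unknownModuleError", "no module with id %d", moduleId)
  e <- net@edges
  internal <- vapply(members, function(v) {
    nb <- c(e[e[, 1L] == v, 2L], e[e[, 2L] == v, 1L])
    sum(mem[nb] == moduleId)
  }, numeric(1))
  external <- vapply(members, function(v) {
    nb <- c(e[e[, 1L] == v, 2L], e[e[, 2L] == v, 1L])
    sum(mem[nb] != moduleId)
  }, numeric(1))
  rk <- rank(c(internal, external))
  stat <- sum(rk[seq_along(internal)])
  crossTies <- length(intersect(unique(internal), unique(external))) > 0L
  if (length(internal) <= 10L && length(external) <= 10L && !crossTies) {
    p <- .exactRankSumP(internal, external)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(internal, external, alternative = "greater",
                         exact = FALSE, correct = TRUE)$p.value)
    if (is.nan(p)) p <- 0.5  # all pooled values equal: no evidence either way
  }
  new("ModuleTest", moduleId = moduleId, members = members,
      internal = unname(internal), external = unname(external),
      statistic = stat, pValue = p, reliable = length(members) >= 4L)
}

setMethod("show", "ModuleTest", function(object) {
  cat(sprintf(
    "ModuleTest: module %d (%d nodes), W = %g, p = %.4g%s\n",
    object@moduleId, length(object@members), object@statistic,
    object@pValue,
    if (object@reliable) "" else " [small module: unreliable]"))
})

#' Test every module of a partition
#'
#' Runs [moduleTest()] for each module and assembles a report table.
#' Raw p-values are reported (no multiple-testing correction by default);
#' `adjust = "holm"` adds a Holm-adjusted column.
#'
#' @param net an [AnatomicalNetwork-class].
#' @param partition a [ModulePartition-class] or named membership vector.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return data.frame with one row per module: module, size, members,
#'   classes, internal and external link counts, W, p (and p_adj when
#'   requested), reliable.
#' @export
moduleTestTable <- function(net, partition, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  mem <- .checkMembership(net, .membershipOf(partition))
  cls <- nodeClasses(net)
  ids <- sort(unique(as.integer(mem)))
  rows <- lapply(ids, function(id) {
    tt <- moduleTest(net, mem, id)
    data.frame(
      module = id, size = length(tt@members),
      members = paste(.csort(tt@members), collapse = ";"),
      classes = paste(unname(cls[.csort(tt@members)]), collapse = ";"),
      internal_links = sum(tt@internal) / 2,
      external_links = sum(tt@external),
      W = tt@statistic, p = tt@pValue, reliable = tt@reliable,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p_adj <- stats::p.adjust(out$p, "holm")
  out
}
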