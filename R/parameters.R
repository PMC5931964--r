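# The six topological descriptors: N, K, D, C, L, H.
#
# N and K come straight from the object; D, C, L and H are computed through
# igraph on the converted graph.  All six are exposed individually and
# bundled by networkParameters().

.connectedOrStop <- function(g, what = "network") {
  comp <- igraph::components(g)
  if (comp$no > 1L)
    .anStop("disconnectedError",
            "%s is disconnected (%d components of sizes %s)",
            what, comp$no, paste(comp$csize, collapse = ", "))
  invisible(comp)
}

#' Degree sequence
#'
#' Per-node degrees in the network's node order; the sum equals twice the
#' number of links.
#'
#' @param net an [AnatomicalNetwork-class].
#' @return integer vector named by node label.
#' @export
setMethod("degreeSequence", "AnatomicalNetwork", function(net) {
  deg <- stats::setNames(rep(0L, nodeCount(net)), nodeLabels(net))
  e <- net@edges
  if (nrow(e)) {
    t1 <- table(factor(e[, 1L], levels = names(deg)))
    t2 <- table(factor(e[, 2L], levels = names(deg)))
    deg <- deg + as.integer(t1) + as.integer(t2)
    names(deg) <- nodeLabels(net)
  }
  deg
})

#' Density of connections (D)
#'
#' The fraction of realised links among the N(N-1)/2 possible ones:
#' `D = 2K / (N(N-1))`.  D is the standard proxy for anatomical
#' complexity: more contacts among parts mean more potential functional
#' interactions.
#'
#' @param net an [AnatomicalNetwork-class] with at least two nodes.
#' @return density fraction in [0, 1].
#' @export
setMethod("networkDensity", "AnatomicalNetwork", function(net) {
  n <- nodeCount(net)
  if (n < 2L)
    .anStop("tooFewNodesError", "density needs at least 2 nodes (got %d)", n)
  2 * edgeCount(net) / (n * (n - 1))
})

#' Mean local clustering coefficient (C)
#'
#' For each node i with degree d >= 2, the local coefficient is the number
#' of links among its neighbours divided by d(d-1)/2; C is the average over
#' nodes and proxies the amount of three-part inter-dependence (triangular
#' loops).  Nodes with degree < 2 have no defined local coefficient; by
#' default they are excluded from the average (`lowDegreeMode = "exclude"`,
#' the average-local-transitivity convention), or they can be counted as 0
#' (`"zero"`).  Returns 0 when no node qualifies.
#'
#' @param net an [AnatomicalNetwork-class].
#' @param lowDegreeMode `"exclude"` (default) or `"zero"`.
#' @return clustering fraction in [0, 1].
#' @export
setMethod("meanClustering", "AnatomicalNetwork",
function(net, lowDegreeMode = c("exclude", "zero")) {
  lowDegreeMode <- match.arg(lowDegreeMode)
  if (nodeCount(net) == 0L) return(0)
  ct <- suppressWarnings(
    igraph::transitivity(asIgraph(net), type = "local", isolates = "NaN"))
  if (lowDegreeMode == "zero") {
    ct[is.nan(ct)] <- 0
    return(mean(ct))
  }
  ct <- ct[!is.nan(ct)]
  if (length(ct) == 0L) return(0)
  mean(ct)
})

#' Characteristic path length (L)
#'
#' The mean shortest-path distance over all unordered node pairs, each
#' link counting one unit.  L proxies the effective proximity of parts: a
#' lower L means anatomical units are topologically closer and can more
#' readily act together.  Defined only for connected networks; a
#' disconnected input raises a `"disconnectedError"` naming the component
#' sizes, unless `largestComponent = TRUE`, which computes L on the
#' largest component with a warning.
#'
#' @param net an [AnatomicalNetwork-class] with at least two nodes.
#' @param largestComponent fall back to the largest component.
#' @return mean geodesic distance (>= 1 for any connected network with
#'   at least one link).
#' @export
setMethod("meanPathLength", "AnatomicalNetwork",
function(net, largestComponent = FALSE) {
  if (nodeCount(net) < 2L)
    .anStop("tooFewNodesError", "path length needs at least 2 nodes")
  g <- asIgraph(net)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    if (!largestComponent)
      .anStop("disconnectedError",
              "network '%s' is disconnected (%d components of sizes %s)",
              networkName(net), comp$no,
              paste(comp$csize, collapse = ", "))
    warning(sprintf(
      "network '%s' is disconnected; L computed on its largest component (%d of %d nodes)",
      networkName(net), max(comp$csize), nodeCount(net)))
    g <- igraph::induced_subgraph(
      g, which(comp$membership == which.max(comp$csize)))
  }
  d <- igraph::distances(g)
  mean(d[upper.tri(d)])
})

#' Degree heterogeneity (H)
#'
#' The coefficient of variation of the degree sequence: standard deviation
#' of the per-node connection counts divided by their mean.  H proxies
#' anisomerism -- how unevenly connected the serially similar parts are; a
#' regular network has H = 0.  The sample (n-1 denominator) standard
#' deviation is the default; `sdType = "population"` uses the n
#' denominator.
#'
#' @param net an [AnatomicalNetwork-class] with at least two nodes and at
#'   least one link.
#' @param sdType `"sample"` (default) or `"population"`.
#' @return dimensionless heterogeneity >= 0.
#' @export
setMethod("degreeHeterogeneity", "AnatomicalNetwork",
function(net, sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  if (nodeCount(net) < 2L)
    .anStop("tooFewNodesError", "heterogeneity needs at least 2 nodes")
  deg <- degreeSequence(net)
  m <- mean(deg)
  if (m == 0)
    .anStop("isolatedNetworkError",
            "all nodes are isolated; mean degree is 0")
  s <- if (sdType == "sample") stats::sd(deg) else
    sqrt(mean((deg - m)^2))
  s / m
})

#' Compute the six network parameters
#'
#' Bundles N, K, [networkDensity()] (D), [meanClustering()] (C),
#' [meanPathLength()] (L) and [degreeHeterogeneity()] (H) for a connected
#' network into a [NetworkParameters-class] object.
#'
#' @param net an [AnatomicalNetwork-class].
#' @param lowDegreeMode passed to [meanClustering()].
#' @param sdType passed to [degreeHeterogeneity()].
#' @param largestComponent passed to [meanPathLength()].
#' @return a [NetworkParameters-class].
#' @examples
#' net <- anatomicalNetwork(
#'   nodes = stats::setNames(rep("bone", 4), letters[1:4]),
#'   edges = rbind(c("a","b"), c("b","c"), c("a","c"), c("a","d")))
#' networkParameters(net)
#' @export
setMethod("networkParameters", "AnatomicalNetwork",
function(net, lowDegreeMode = c("exclude", "zero"),
         sdType = c("sample", "population"), largestComponent = FALSE) {
  NetworkParameters(
    name = networkName(net),
    N = nodeCount(net),
    K = edgeCount(net),
    D = networkDensity(net),
    C = meanClustering(net, match.arg(lowDegreeMode)),
    L = meanPathLength(net, largestComponent = largestComponent),
    H = degreeHeterogeneity(net, match.arg(sdType)))
})

#' Construct a NetworkParameters object from known values
#'
#' Used to replay published parameter rows (see [readParameterTable()]).
#'
#' @param name network tag.
#' @param N,K,D,C,L,H the six parameter values.
#' @return a [NetworkParameters-class].
#' @export
NetworkParameters <- function(name, N, K, D, C, L, H) {
  # Class must be matched exactly: a literal `C =` argument would
  # partially match new()'s `Class` formal otherwise.
  do.call(methods::new,
          list(Class = "NetworkParameters", name = as.character(name)[1L],
               N = as.numeric(N), K = as.numeric(K), D = as.numeric(D),
               C = as.numeric(C), L = as.numeric(L), H = as.numeric(H)))
}

#' @rdname accessors
#' @export
setMethod("networkName", "NetworkParameters", function(x) x@name)

#' Coerce parameters to a one-row data.frame
#'
#' @param x a [NetworkParameters-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with columns network, N, K, D, C, L, H.
#' @export
as.data.frame.NetworkParameters <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(network = x@name, N = x@N, K = x@K, D = x@D, C = x@C,
             L = x@L, H = x@H, stringsAsFactors = FALSE)
}

setMethod("show", "NetworkParameters", function(object) {
  cat(sprintf(
    "NetworkParameters '%s': N=%g K=%g D=%.3f C=%.3f L=%.3f H=%.3f\n",
    object@name, object@N, object@K, object@D, object@C, object@L,
    object@H))
})

#' Extract parameter values as a named vector
#'
#' @param p a [NetworkParameters-class].
#' @return named numeric vector (N, K, D, C, L, H).
#' @export
parameterVector <- function(p) {
  c(N = p@N, K = p@K, D = p@D, C = p@C, L = p@L, H = p@H)
}
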