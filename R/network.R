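# Construction, validation and slicing of anatomical networks.

.canonicalEdges <- function(edges) {
  if (is.null(edges) || NROW(edges) == 0L)
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  edges <- as.matrix(edges)
  storage.mode(edges) <- "character"
  a <- edges[, 1L]
  b <- edges[, 2L]
  swap <- .corder2(a, b)
  from <- ifelse(swap, a, b)
  to <- ifelse(swap, b, a)
  m <- cbind(from = from, to = to)
  m[.corder(m[, 1L], m[, 2L]), , drop = FALSE]
}

# TRUE where a <= b in C-locale order
.corder2 <- function(a, b) {
  # radix-based pairwise comparison without locale effects
  n <- length(a)
  if (n == 0L) return(logical(0))
  vapply(seq_len(n), function(i) {
    .corder(c(a[i], b[i]))[1L] == 1L || a[i] == b[i]
  }, logical(1))
}

#' Create an anatomical network
#'
#' Builds a validated [AnatomicalNetwork-class] from a node table and an
#' edge list.  Edges are stored canonically so that two equal networks
#' compare identical slot-by-slot.
#'
#' @param nodes data.frame with columns `label` and `class`, or a named
#'   character vector (names = labels, values = classes).
#' @param edges two-column matrix or data.frame of node labels (one row
#'   per undirected link); may be empty.
#' @param name single character tag.
#' @param validate if TRUE (default) all invariants are checked and the
#'   first violations are raised as an error of class `"invalidNetworkError"`.
#' @return an [AnatomicalNetwork-class] object.
#' @seealso [validateNetwork()], [readAnatomicalNetwork()]
#' @export
anatomicalNetwork <- function(nodes, edges = NULL, name = "network",
                              validate = TRUE) {
  if (!is.data.frame(nodes)) {
    nodes <- data.frame(label = names(nodes), class = unname(nodes),
                        stringsAsFactors = FALSE)
  }
  nodes <- data.frame(label = as.character(nodes$label),
                      class = as.character(nodes$class),
                      stringsAsFactors = FALSE)
  net <- new("AnatomicalNetwork", name = as.character(name)[1L],
             nodes = nodes, edges = .canonicalEdges(edges))
  if (validate) {
    bad <- validateNetwork(net)
    if (length(bad))
      .anStop("invalidNetworkError", "invalid network '%s': %s",
              networkName(net), paste(bad, collapse = "; "))
  }
  net
}

#' Accessors for anatnet classes
#'
#' `networkName`, `nodeLabels`, `nodeClasses` (a named character vector),
#' `edgeTable` (two-column data.frame), `nodeCount` (N) and `edgeCount` (K)
#' read an [AnatomicalNetwork-class]; `moduleMembership`, `qValue` and
#' `qStandardError` read a [ModulePartition-class]; `ardPercent` reads a
#' [ComparisonResult-class].
#'
#' @param x the object to access.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("networkName", "AnatomicalNetwork", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("nodeLabels", "AnatomicalNetwork", function(x) x@nodes$label)

#' @rdname accessors
#' @export
setMethod("nodeClasses", "AnatomicalNetwork", function(x) {
  stats::setNames(x@nodes$class, x@nodes$label)
})

#' @rdname accessors
#' @export
setMethod("edgeTable", "AnatomicalNetwork", function(x) {
  data.frame(from = x@edges[, 1L], to = x@edges[, 2L],
             stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("nodeCount", "AnatomicalNetwork", function(x) nrow(x@nodes))

#' @rdname accessors
#' @export
setMethod("edgeCount", "AnatomicalNetwork", function(x) nrow(x@edges))

setMethod("show", "AnatomicalNetwork", function(object) {
  cls <- table(factor(object@nodes$class, levels = .NODE_CLASSES))
  cat(sprintf("AnatomicalNetwork '%s': %d nodes (%s), %d links\n",
              object@name, nodeCount(object),
              paste(sprintf("%d %s", as.integer(cls), names(cls)),
                    collapse = ", "),
              edgeCount(object)))
})

#' List invariant violations of a network
#'
#' Reports (never throws) every violated invariant: empty or duplicated
#' labels, classes outside bone/cartilage/muscle, self-loops, duplicate
#' links, and links whose endpoints are not declared nodes.  Each
#' violation names the offending node or link.
#'
#' @param net an [AnatomicalNetwork-class] (possibly hand-built and
#'   malformed).
#' @return character vector of violation descriptions; empty when all
#'   invariants hold.
#' @export
setMethod("validateNetwork", "AnatomicalNetwork", function(net) {
  out <- character(0)
  lab <- net@nodes$label
  cls <- net@nodes$class
  if (anyNA(lab) || any(!nzchar(lab)))
    out <- c(out, "node with empty label")
  dup <- unique(lab[duplicated(lab)])
  if (length(dup))
    out <- c(out, sprintf("duplicated node label '%s'", dup))
  badc <- which(!cls %in% .NODE_CLASSES)
  if (length(badc))
    out <- c(out, sprintf(
      "node '%s' has class '%s' (must be bone, cartilage or muscle)",
      lab[badc], cls[badc]))
  e <- net@edges
  if (nrow(e)) {
    self <- which(e[, 1L] == e[, 2L])
    if (length(self))
      out <- c(out, sprintf("self-loop on node '%s'", e[self, 1L]))
    key <- paste(e[, 1L], e[, 2L], sep = "\r")
    dupe <- which(duplicated(key))
    if (length(dupe))
      out <- c(out, sprintf("duplicate link '%s'--'%s'",
                            e[dupe, 1L], e[dupe, 2L]))
    miss <- setdiff(unique(c(e[, 1L], e[, 2L])), lab)
    if (length(miss))
      out <- c(out, sprintf("link endpoint '%s' is not a declared node",
                            miss))
  }
  out
})

#' Induced subnetwork on a set of node classes
#'
#' Restricts a network to the nodes whose class lies in `keepClasses` and
#' the links among them.  `c("bone", "cartilage")` gives the skeletal
#' network, `"muscle"` the muscular one; keeping all three classes returns
#' an identical copy.  The subnetwork name is suffixed with the kept level.
#'
#' @param net an [AnatomicalNetwork-class].
#' @param keepClasses non-empty subset of
#'   `c("bone", "cartilage", "muscle")`.
#' @return the induced [AnatomicalNetwork-class].
#' @export
setMethod("subNetwork", "AnatomicalNetwork", function(net, keepClasses) {
  if (length(keepClasses) == 0L)
    .anStop("emptyClassSetError", "'keepClasses' must be non-empty")
  bad <- setdiff(keepClasses, .NODE_CLASSES)
  if (length(bad))
    .anStop("unknownClassError", "unknown node class(es): %s",
            paste(bad, collapse = ", "))
  keep <- net@nodes$class %in% keepClasses
  nodes <- net@nodes[keep, , drop = FALSE]
  rownames(nodes) <- NULL
  inset <- net@edges[, 1L] %in% nodes$label & net@edges[, 2L] %in% nodes$label
  suffix <- if (setequal(keepClasses, .NODE_CLASSES)) "" else
    if (setequal(keepClasses, c("bone", "cartilage"))) "_skeletal" else
    if (identical(sort(keepClasses), "muscle")) "_muscular" else
    paste0("_", paste(sort(keepClasses), collapse = "+"))
  anatomicalNetwork(nodes, net@edges[inset, , drop = FALSE],
                    name = paste0(net@name, suffix))
})

#' Consensus presence coding across specimens
#'
#' A structure (muscle or attachment) is coded present for a species when
#' it was observed in strictly more than 50\% of the examined specimens;
#' exactly half is coded absent.
#'
#' @param observations non-empty logical vector, one flag per specimen.
#' @return single logical: consensus presence.
#' @examples
#' consensusPresence(c(rep(TRUE, 20), rep(FALSE, 18)))  # 52.6% -> TRUE
#' consensusPresence(c(rep(TRUE, 19), rep(FALSE, 19)))  # 50%   -> FALSE
#' @export
consensusPresence <- function(observations) {
  if (length(observations) == 0L)
    .anStop("emptyObservationsError",
            "at least one specimen observation is required")
  mean(as.logical(observations)) > 0.5
}

#' Convert to an igraph object
#'
#' Returns the network as an undirected [igraph::igraph] graph with a
#' `class` vertex attribute, in the network's node order.  Used internally
#' for the standard topological computations; exported for interoperation.
#'
#' @param net an [AnatomicalNetwork-class].
#' @return an igraph graph.
#' @export
setMethod("asIgraph", "AnatomicalNetwork", function(net) {
  igraph::graph_from_data_frame(edgeTable(net), directed = FALSE,
                                vertices = net@nodes)
})
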