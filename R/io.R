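# Reading and writing networks and parameter tables.
#
# Canonical on-disk dialect: a square adjacency CSV whose first row and
# first column carry the node labels and whose cells are strictly "0"/"1",
# plus a two-column CSV (label,class) for the node classes.

#' Read an anatomical network from labelled CSV files
#'
#' Loads a square 0/1 adjacency matrix (first row and column are node
#' labels) and a two-column `label,class` table, and returns the validated
#' network.  The coding is strict: any of the following raises a distinct,
#' typed validation error rather than being repaired silently --
#' \describe{
#'   \item{nonsquareError}{the table is not square;}
#'   \item{labelMismatchError}{row and column label sets differ;}
#'   \item{invalidEntryError}{a cell is not "0" or "1";}
#'   \item{asymmetryError}{`A[i,j] != A[j,i]` (the offending cell is
#'     named); pass `symmetrize = TRUE` to opt in to `max(A, t(A))`;}
#'   \item{diagonalError}{a 1 on the diagonal (a unit cannot contact
#'     itself);}
#'   \item{missingClassError}{a label without a class entry.}
#' }
#'
#' @param adjacency path to the adjacency CSV.
#' @param classes path to the `label,class` CSV (header required).
#' @param name network tag; defaults to the adjacency file name.
#' @param symmetrize accept asymmetric input as `max(A, t(A))`.
#' @return an [AnatomicalNetwork-class]; its [edgeCount()] equals the
#'   number of 1 entries above the diagonal.
#' @seealso [writeAnatomicalNetwork()]
#' @export
readAnatomicalNetwork <- function(adjacency, classes, name = NULL,
                                  symmetrize = FALSE) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(adjacency))
  tab <- utils::read.csv(adjacency, check.names = FALSE,
                         colClasses = "character")
  labs <- as.character(tab[[1L]])
  A <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(A) <- labs
  if (nrow(A) != ncol(A))
    .anStop("nonsquareError",
            "adjacency table is %d x %d, not square", nrow(A), ncol(A))
  if (!setequal(rownames(A), colnames(A)))
    .anStop("labelMismatchError",
            "row and column labels differ as sets (e.g. %s)",
            paste(utils::head(c(setdiff(rownames(A), colnames(A)),
                                setdiff(colnames(A), rownames(A))), 3L),
                  collapse = ", "))
  A <- A[, rownames(A), drop = FALSE]
  bad <- which(!A %in% c("0", "1"))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(A)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(A)) + 1L
    .anStop("invalidEntryError",
            "entry (%s, %s) is '%s'; cells must be 0 or 1",
            rownames(A)[i], colnames(A)[j], A[bad[1L]])
  }
  M <- matrix(as.integer(A), nrow(A), dimnames = dimnames(A))
  if (!isSymmetric(unname(M))) {
    if (symmetrize) {
      M <- pmax(M, t(M))
    } else {
      d <- which(M != t(M), arr.ind = TRUE)[1L, ]
      .anStop("asymmetryError",
              "A[%s, %s] = %d but A[%s, %s] = %d; matrix must be symmetric",
              rownames(M)[d[1L]], colnames(M)[d[2L]], M[d[1L], d[2L]],
              rownames(M)[d[2L]], colnames(M)[d[1L]], M[d[2L], d[1L]])
    }
  }
  if (any(diag(M) == 1L))
    .anStop("diagonalError", "diagonal entry for '%s' is 1; must be 0",
            rownames(M)[which(diag(M) == 1L)[1L]])
  cl <- utils::read.csv(classes, colClasses = "character")
  if (!all(c("label", "class") %in% names(cl)))
    .anStop("missingClassError",
            "class table must have columns 'label' and 'class'")
  miss <- setdiff(rownames(M), cl$label)
  if (length(miss))
    .anStop("missingClassError", "no class entry for node(s): %s",
            paste(utils::head(miss, 5L), collapse = ", "))
  cmap <- stats::setNames(cl$class, cl$label)
  up <- which(upper.tri(M) & M == 1L, arr.ind = TRUE)
  edges <- cbind(rownames(M)[up[, 1L]], colnames(M)[up[, 2L]])
  nodes <- data.frame(label = rownames(M),
                      class = unname(cmap[rownames(M)]),
                      stringsAsFactors = FALSE)
  anatomicalNetwork(nodes, edges, name = name)
}

#' Write a network as adjacency + class CSV files
#'
#' Inverse of [readAnatomicalNetwork()]: a round-trip reproduces the node
#' set, class map and edge set exactly.
#'
#' @param net an [AnatomicalNetwork-class].
#' @param adjacency,classes output CSV paths.
#' @return invisibly, the two paths.
#' @export
writeAnatomicalNetwork <- function(net, adjacency, classes) {
  labs <- nodeLabels(net)
  M <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  e <- net@edges
  if (nrow(e)) {
    M[cbind(e[, 1L], e[, 2L])] <- 1L
    M[cbind(e[, 2L], e[, 1L])] <- 1L
  }
  df <- data.frame(label = labs, M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, adjacency, row.names = FALSE, quote = FALSE)
  utils::write.csv(net@nodes, classes, row.names = FALSE, quote = FALSE)
  invisible(c(adjacency = adjacency, classes = classes))
}

#' Export a network to GraphML
#'
#' @param net an [AnatomicalNetwork-class].
#' @param file output path.
#' @return invisibly, `file`.
#' @export
exportGraphML <- function(net, file) {
  igraph::write_graph(asIgraph(net), file, format = "graphml")
  invisible(file)
}

#' Export a network as a two-column edge list (TSV)
#'
#' @param net an [AnatomicalNetwork-class].
#' @param file output path.
#' @return invisibly, `file`.
#' @export
exportEdgeList <- function(net, file) {
  utils::write.table(edgeTable(net), file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Read a parameter table (Table-1-style TSV)
#'
#' Reads rows of published or precomputed six-parameter sets, one network
#' per row, with columns `network, N, K, D, C, L, H`.  This is the replay
#' input: ARD comparisons can be reproduced from printed parameter values
#' without access to the underlying adjacency matrices.
#'
#' @param file TSV path.
#' @return named list of [NetworkParameters-class] objects.
#' @seealso [referenceParameters()], [ardMatrix()]
#' @export
readParameterTable <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("network", "N", "K", "D", "C", "L", "H")
  if (!all(need %in% names(df)))
    .anStop("parameterTableError",
            "parameter table must have columns %s",
            paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    NetworkParameters(name = df$network[i], N = df$N[i], K = df$K[i],
                      D = df$D[i], C = df$C[i], L = df$L[i], H = df$H[i])
  })
  stats::setNames(out, df$network)
}

#' Published limb network parameters of humans and chimpanzees
#'
#' The six-parameter descriptions (N, K, D, C, L, H) of the fore- and
#' hindlimb musculoskeletal networks of \emph{Homo sapiens},
#' \emph{Pan troglodytes} and \emph{Pan paniscus}, as published for the
#' dissection-derived networks.  Shipped with the package so that the
#' ARD similarity analysis can be replayed without the original adjacency
#' matrices.
#'
#' @return named list of six [NetworkParameters-class] objects.
#' @examples
#' ref <- referenceParameters()
#' ard(ref$Pan_troglodytes_forelimb, ref$Pan_paniscus_forelimb)
#' @export
referenceParameters <- function() {
  readParameterTable(system.file("extdata", "hominid_limb_parameters.tsv",
                                 package = "anatnet", mustWork = TRUE))
}
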