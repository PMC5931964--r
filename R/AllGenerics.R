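#' @rdname accessors
#' @export
setGeneric("networkName", function(x) standardGeneric("networkName"))

#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname accessors
#' @export
setGeneric("nodeClasses", function(x) standardGeneric("nodeClasses"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' @rdname accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname validateNetwork
#' @export
setGeneric("validateNetwork", function(net) standardGeneric("validateNetwork"))

#' @rdname subNetwork
#' @export
setGeneric("subNetwork",
           function(net, keepClasses) standardGeneric("subNetwork"))

#' @rdname asIgraph
#' @export
setGeneric("asIgraph", function(net) standardGeneric("asIgraph"))

#' @rdname degreeSequence
#' @export
setGeneric("degreeSequence", function(net) standardGeneric("degreeSequence"))

#' @rdname networkDensity
#' @export
setGeneric("networkDensity", function(net) standardGeneric("networkDensity"))

#' @rdname meanClustering
#' @export
setGeneric("meanClustering",
  function(net, lowDegreeMode = c("exclude", "zero"))
    standardGeneric("meanClustering"))

#' @rdname meanPathLength
#' @export
setGeneric("meanPathLength",
  function(net, largestComponent = FALSE)
    standardGeneric("meanPathLength"))

#' @rdname degreeHeterogeneity
#' @export
setGeneric("degreeHeterogeneity",
  function(net, sdType = c("sample", "population"))
    standardGeneric("degreeHeterogeneity"))

#' @rdname networkParameters
#' @export
setGeneric("networkParameters",
  function(net, lowDegreeMode = c("exclude", "zero"),
           sdType = c("sample", "population"), largestComponent = FALSE)
    standardGeneric("networkParameters"))

#' @rdname walktrapTree
#' @export
setGeneric("walktrapTree",
  function(net, steps = 3L) standardGeneric("walktrapTree"))

#' @rdname bestPartition
#' @export
setGeneric("bestPartition",
  function(tree, net) standardGeneric("bestPartition"))

#' @rdname accessors
#' @export
setGeneric("moduleMembership",
           function(x) standardGeneric("moduleMembership"))

#' @rdname accessors
#' @export
setGeneric("qValue", function(x) standardGeneric("qValue"))

#' @rdname accessors
#' @export
setGeneric("qStandardError", function(x) standardGeneric("qStandardError"))

#' @rdname ard
#' @export
setGeneric("ard", function(a, b) standardGeneric("ard"))

#' @rdname accessors
#' @export
setGeneric("ardPercent", function(x) standardGeneric("ardPercent"))

#' @rdname generateLimbNetwork
#' @export
setGeneric("generateLimbNetwork",
           function(spec) standardGeneric("generateLimbNetwork"))

#' @rdname runAnalysis
#' @export
setGeneric("runAnalysis", function(config) standardGeneric("runAnalysis"))

#' @rdname writeReport
#' @export
setGeneric("writeReport",
  function(report, outdir, force = FALSE) standardGeneric("writeReport"))
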