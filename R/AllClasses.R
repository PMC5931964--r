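#' @import methods
NULL

.NODE_CLASSES <- c("bone", "cartilage", "muscle")

#' AnatomicalNetwork: a simple undirected network of anatomical units
#'
#' Nodes are labelled anatomical units (bones, cartilages, muscles); links
#' are physical contacts between pairs of units: articulations between
#' skeletal elements, attachments of muscles onto bones, and blending
#' (fibrous fusion) between muscles.  The graph is simple and undirected:
#' no self-loops, no duplicate links, symmetric adjacency.
#'
#' Objects are created with [anatomicalNetwork()] or read from labelled
#' adjacency matrices with [readAnatomicalNetwork()].
#'
#' @slot name single character tag for the network (e.g. "homo_forelimb").
#' @slot nodes data.frame with columns `label` (unique, non-empty character)
#'   and `class` (one of `"bone"`, `"cartilage"`, `"muscle"`).
#' @slot edges character matrix with two columns; each row is one undirected
#'   link, stored canonically (endpoints in C-locale sorted order, rows
#'   sorted), so identical networks have identical slots.
#'
#' @seealso [networkParameters()], [walktrapTree()], [subNetwork()]
#' @examples
#' net <- anatomicalNetwork(
#'   nodes = data.frame(label = c("humerus", "ulna", "m_brachialis"),
#'                      class = c("bone", "bone", "muscle")),
#'   edges = rbind(c("humerus", "ulna"),
#'                 c("humerus", "m_brachialis"),
#'                 c("ulna", "m_brachialis")),
#'   name = "toy_arm")
#' net
#' @export
setClass("AnatomicalNetwork",
  representation(name = "character", nodes = "data.frame", edges = "matrix"))

setValidity("AnatomicalNetwork", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L)
    msg <- c(msg, "'name' must be a single character string")
  if (!all(c("label", "class") %in% names(object@nodes)))
    msg <- c(msg, "'nodes' must have columns 'label' and 'class'")
  if (ncol(object@edges) != 2L && !(nrow(object@edges) == 0L))
    msg <- c(msg, "'edges' must have two columns")
  if (length(msg)) msg else TRUE
})

#' NetworkParameters: the six topological descriptors of a network
#'
#' Bundles the six parameters used to characterise anatomical organisation:
#' number of nodes (N) and of connections (K); density of connections
#' (D = K / (N(N-1)/2)), a proxy for anatomical complexity; mean local
#' clustering coefficient (C), a proxy for local three-part integration;
#' characteristic (mean shortest) path length (L), a proxy for effective
#' proximity of parts; and degree heterogeneity (H = sd/mean of the degree
#' sequence), a proxy for anisomerism.
#'
#' Compute from a network with [networkParameters()], or build directly
#' from known values with [NetworkParameters()] (e.g. to replay published
#' parameter tables).
#'
#' @slot name network tag the parameters belong to.
#' @slot N,K,D,C,L,H single numeric values (see Description).
#' @export
setClass("NetworkParameters",
  representation(name = "character", N = "numeric", K = "numeric",
                 D = "numeric", C = "numeric", L = "numeric", H = "numeric"))

setValidity("NetworkParameters", function(object) {
  msg <- character(0)
  for (s in c("N", "K", "D", "C", "L", "H")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v))
      msg <- c(msg, sprintf("'%s' must be a single non-missing number", s))
  }
  if (!length(msg)) {
    if (object@D < 0 || object@D > 1) msg <- c(msg, "'D' must lie in [0,1]")
    if (object@C < 0 || object@C > 1) msg <- c(msg, "'C' must lie in [0,1]")
    if (object@H < 0)                 msg <- c(msg, "'H' must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' WalktrapTree: merge tree of the short-random-walk agglomeration
#'
#' Records the full agglomerative history of the random-walk community
#' algorithm: starting from one singleton community per node, the two
#' adjacent communities whose merger least increases the mean squared
#' walk-profile distance are merged, until a single community remains
#' (exactly N - 1 merges for a connected network).  Any level of the tree
#' can be cut into a partition; [bestPartition()] selects the level that
#' maximises Newman-Girvan modularity Q.
#'
#' @slot labels node labels in the canonical (C-locale sorted) order used
#'   during agglomeration; initial singleton community i holds `labels[i]`.
#' @slot merges integer matrix (N-1 rows, 2 columns): community ids merged
#'   at each step; the community created at step s has id N + s.
#' @slot deltaSigma numeric vector of the Ward-style merge costs.
#' @slot steps length of the random walks used (t).
#' @slot networkName tag of the network the tree was grown on.
#' @export
setClass("WalktrapTree",
  representation(labels = "character", merges = "matrix",
                 deltaSigma = "numeric", steps = "integer",
                 networkName = "character"))

setValidity("WalktrapTree", function(object) {
  n <- length(object@labels)
  if (n >= 2 && !identical(dim(object@merges), c(n - 1L, 2L)))
    return(sprintf("'merges' must be a (%d x 2) matrix for %d labels",
                   n - 1L, n))
  TRUE
})

#' ModulePartition: a node-to-module assignment with its modularity
#'
#' A hard partition of the network's nodes into connectivity modules,
#' together with its Newman-Girvan modularity Q and (once computed with
#' [jackknifeQSE()]) the jackknife standard error of Q.
#'
#' @slot membership named integer vector: node label -> module id; module
#'   ids are contiguous integers starting at 1.
#' @slot q Newman-Girvan modularity of the partition (in [-0.5, 1]).
#' @slot qSE jackknife standard error of `q`; `NA` until computed.
#' @slot networkName tag of the partitioned network.
#' @export
setClass("ModulePartition",
  representation(membership = "integer", q = "numeric", qSE = "numeric",
                 networkName = "character"))

setValidity("ModulePartition", function(object) {
  m <- object@membership
  if (is.null(names(m)) || anyNA(m))
    return("'membership' must be a complete named integer vector")
  ids <- sort(unique(as.integer(m)))
  if (length(ids) && !identical(ids, seq_along(ids)))
    return("module ids must be contiguous integers starting at 1")
  if (length(object@q) == 1L && !is.na(object@q) &&
      (object@q < -0.5 - 1e-12 || object@q > 1 + 1e-12))
    return("'q' must lie in [-0.5, 1]")
  TRUE
})

#' ModuleTest: internal-vs-external connectivity test of one module
#'
#' Result of the one-sided two-sample Wilcoxon rank-sum test comparing, for
#' every node of a module, its number of connections to nodes of the same
#' module (internal) against its connections to the rest of the network
#' (external).  Under the definition of a connectivity module, internal
#' connections are expected to exceed external ones (H0: equal;
#' Ha: internal > external).  Small modules give unreliable p-values and
#' are flagged.
#'
#' @slot moduleId integer id of the tested module.
#' @slot members labels of the module's nodes.
#' @slot internal,external per-member counts of internal / external links.
#' @slot statistic rank-sum of the internal sample in the pooled ranking.
#' @slot pValue one-sided p-value (exact enumeration for small tie-free
#'   samples, tie- and continuity-corrected normal approximation otherwise).
#' @slot reliable FALSE when the module has fewer than 4 nodes.
#' @export
setClass("ModuleTest",
  representation(moduleId = "integer", members = "character",
                 internal = "numeric", external = "numeric",
                 statistic = "numeric", pValue = "numeric",
                 reliable = "logical"))

setValidity("ModuleTest", function(object) {
  n <- length(object@members)
  if (length(object@internal) != n || length(object@external) != n)
    return("'internal' and 'external' must have one entry per member")
  if (length(object@pValue) == 1L &&
      (object@pValue <= 0 || object@pValue > 1))
    return("'pValue' must lie in (0, 1]")
  TRUE
})

#' ComparisonResult: parameter-wise similarity of two networks
#'
#' Holds, for a pair of networks, the relative difference of each of the
#' six parameters (absolute difference normalised by the pair mean) and
#' their average expressed as a percentage -- the Average Relative
#' Difference (ARD).  ARD is 0 exactly when all six parameters coincide,
#' and is symmetric in its two arguments.
#'
#' @slot labelA,labelB names of the compared networks.
#' @slot perParameter named numeric vector of the six relative-difference
#'   fractions (names N, K, D, C, L, H).
#' @slot ardPercent mean of the six fractions times 100.
#' @export
setClass("ComparisonResult",
  representation(labelA = "character", labelB = "character",
                 perParameter = "numeric", ardPercent = "numeric"))

setValidity("ComparisonResult", function(object) {
  if (!identical(names(object@perParameter), c("N", "K", "D", "C", "L", "H")))
    return("'perParameter' must be named N, K, D, C, L, H")
  if (object@ardPercent < -1e-12)
    return("'ardPercent' must be >= 0")
  TRUE
})

#' LimbSpec: generative description of a synthetic limb network
#'
#' Describes a limb-like musculoskeletal network with planted modular
#' structure: a serial chain of long bones (stylopod + zeugopod), a block
#' of mesopodial elements (carpals/tarsals), digit rays (optional
#' metapodial plus a phalanx chain), and three kinds of muscles --
#' intrinsic serial digit muscles confined to one ray (contrahentes-like),
#' muscles shared across a subset of rays, and extrinsic muscles running
#' from the long-bone chain to the digits.  Muscle-muscle blending links
#' are added at random between muscles that share an attachment bone.
#'
#' Build with [limbSpec()] or use a ready-made [presetLimbSpec()].
#'
#' @slot name tag used for the generated network.
#' @slot longBoneChain number of serially articulated proximal bones.
#' @slot mesopodNodes number of mesopodial elements.
#' @slot mesopodDensity target fraction of realised intra-mesopod
#'   articulations (of the possible pairs).
#' @slot digitCount number of digit rays.
#' @slot phalangesPerDigit integer vector, phalanx count per ray.
#' @slot metapodialPerDigit logical: give each ray a metapodial bone.
#' @slot serialDigitMuscles logical vector (one per digit): dedicated
#'   intrinsic muscles for that ray.
#' @slot intrinsicMusclesPerDigit muscles added per flagged ray.
#' @slot sharedDigitMuscles list of `list(digits=, count=)` entries for
#'   muscles spanning several rays.
#' @slot extrinsicMuscles number of chain-to-digit muscles.
#' @slot muscleBlendingProbability probability of a blending link between
#'   two muscles sharing an attachment bone.
#' @slot seed integer seed governing all random draws.
#' @export
setClass("LimbSpec",
  representation(name = "character", longBoneChain = "integer",
                 mesopodNodes = "integer", mesopodDensity = "numeric",
                 digitCount = "integer", phalangesPerDigit = "integer",
                 metapodialPerDigit = "logical",
                 serialDigitMuscles = "logical",
                 intrinsicMusclesPerDigit = "integer",
                 sharedDigitMuscles = "list", extrinsicMuscles = "integer",
                 muscleBlendingProbability = "numeric", seed = "integer"))

setValidity("LimbSpec", function(object) {
  msg <- character(0)
  cnt <- c(longBoneChain = object@longBoneChain,
           mesopodNodes = object@mesopodNodes,
           digitCount = object@digitCount,
           intrinsicMusclesPerDigit = object@intrinsicMusclesPerDigit,
           extrinsicMuscles = object@extrinsicMuscles)
  if (any(cnt < 0L)) msg <- c(msg, "all counts must be >= 0")
  if (length(object@phalangesPerDigit) != object@digitCount)
    msg <- c(msg, "'phalangesPerDigit' must have one entry per digit")
  if (length(object@serialDigitMuscles) != object@digitCount)
    msg <- c(msg, "'serialDigitMuscles' must have one flag per digit")
  if (object@muscleBlendingProbability < 0 ||
      object@muscleBlendingProbability > 1)
    msg <- c(msg, "'muscleBlendingProbability' must lie in [0,1]")
  if (object@mesopodDensity < 0 || object@mesopodDensity > 1)
    msg <- c(msg, "'mesopodDensity' must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' AnalysisConfig: configuration of a full analysis run
#'
#' Describes one end-to-end run: which networks to load (adjacency +
#' class CSV paths) or simulate (preset names), which induced levels to
#' analyse (full musculoskeletal, skeletal = bones + cartilages, muscular
#' = muscles only), and the numerical conventions (walk length, treatment
#' of low-degree nodes in C, standard-deviation convention in H).
#' Create with [analysisConfig()] and execute with [runAnalysis()].
#'
#' @slot inputs list of `list(name=, adjacency=, classes=)` file inputs.
#' @slot presets character vector of [presetLimbSpec()] names to simulate.
#' @slot parameterTable path to a parameter TSV for replay mode ("" = none):
#'   ARD is computed directly from published parameter rows, no graphs.
#' @slot levels subset of `c("full", "skeletal", "muscular")`.
#' @slot steps random-walk length for module detection.
#' @slot clusteringMode `"exclude"` or `"zero"` (see [meanClustering()]).
#' @slot sdType `"sample"` or `"population"` (see [degreeHeterogeneity()]).
#' @slot largestComponent analyse the largest component of a disconnected
#'   (sub)network instead of failing.
#' @slot symmetrize accept asymmetric adjacency input as max(A, t(A)).
#' @slot seed integer seed for simulated inputs.
#' @export
setClass("AnalysisConfig",
  representation(inputs = "list", presets = "character",
                 parameterTable = "character", levels = "character",
                 steps = "integer", clusteringMode = "character",
                 sdType = "character", largestComponent = "logical",
                 symmetrize = "logical", seed = "integer"))

setValidity("AnalysisConfig", function(object) {
  msg <- character(0)
  if (length(object@inputs) == 0L && length(object@presets) == 0L &&
      !nzchar(object@parameterTable))
    msg <- c(msg, "at least one input, preset or parameter table is required")
  if (object@steps < 1L) msg <- c(msg, "'steps' must be >= 1")
  if (!all(object@levels %in% c("full", "skeletal", "muscular")))
    msg <- c(msg, "'levels' must be among full/skeletal/muscular")
  if (length(msg)) msg else TRUE
})

#' AnalysisReport: the assembled results of one analysis run
#'
#' @slot parameters data.frame with one row per network and level
#'   (columns network, level, N, K, D, C, L, H).
#' @slot partitions named list of [ModulePartition-class] objects, keyed
#'   `"<network>|<level>"`.
#' @slot moduleTests data.frame of per-module test results across all
#'   partitioned networks.
#' @slot ard named list (one entry per level) of symmetric ARD matrices.
#' @slot meta list of run metadata: settings, seed, versions.
#' @seealso [runAnalysis()], [writeReport()]
#' @export
setClass("AnalysisReport",
  representation(parameters = "data.frame", partitions = "list",
                 moduleTests = "data.frame", ard = "list", meta = "list"))
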