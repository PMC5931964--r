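# Inter-network similarity: per-parameter relative differences and the
# Average Relative Difference (ARD).
#
# The defining convention of this module: the relative difference of a
# parameter between two networks is the absolute difference normalised by
# the pair mean, |a - b| / ((a + b) / 2), and the ARD is the mean of the
# six relative differences over {N, K, D, C, L, H}, expressed as a
# percentage.  This reconstruction reproduces, from the published rounded
# parameter rows, four independently printed percentages (8.1, 5.3, 5.3
# and 1.3) exactly at 1-decimal rounding.  Comparisons involving the
# Homo sapiens forelimb row do not replay exactly from the rounded table
# (its L is printed at lower precision), so published values for those
# pairs carry the authors' unrounded inputs.

#' Relative difference of two non-negative values
#'
#' `|a - b| / ((a + b) / 2)`: the absolute difference normalised by the
#' pair mean, the symmetric, scale-free elementary term of the ARD.
#'
#' @param a,b non-negative numbers, not both zero.
#' @return relative-difference fraction (0 when `a == b`).
#' @examples
#' relativeDifference(0.051, 0.047)  # 0.0816
#' @export
relativeDifference <- function(a, b) {
  if (a < 0 || b < 0)
    .anStop("negativeValueError",
            "relative difference needs non-negative values")
  if (a == 0 && b == 0)
    .anStop("zeroPairError",
            "relative difference is undefined for a = b = 0")
  abs(a - b) / ((a + b) / 2)
}

#' Average Relative Difference between two parameter sets
#'
#' Applies [relativeDifference()] to each of the six parameters and
#' averages; the result times 100 is the ARD percentage used to compare
#' limb networks within and between species (parameters equal in both
#' networks, including jointly zero ones, contribute 0).
#'
#' @param a,b [NetworkParameters-class] objects (or
#'   [AnatomicalNetwork-class]es, whose parameters are computed with
#'   defaults first).
#' @return a [ComparisonResult-class].
#' @examples
#' ref <- referenceParameters()
#' ard(ref$Pan_troglodytes_forelimb, ref$Pan_paniscus_forelimb)  # 5.3%
#' @export
setMethod("ard", c("NetworkParameters", "NetworkParameters"),
function(a, b) {
  va <- parameterVector(a)
  vb <- parameterVector(b)
  rd <- vapply(names(va), function(p) {
    if (va[[p]] == vb[[p]]) 0 else relativeDifference(va[[p]], vb[[p]])
  }, numeric(1))
  new("ComparisonResult", labelA = a@name, labelB = b@name,
      perParameter = rd, ardPercent = 100 * mean(rd))
})

#' @rdname ard
#' @export
setMethod("ard", c("AnatomicalNetwork", "AnatomicalNetwork"),
function(a, b) {
  ard(networkParameters(a), networkParameters(b))
})

#' @rdname accessors
#' @export
setMethod("ardPercent", "ComparisonResult", function(x) x@ardPercent)

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("ComparisonResult: '%s' vs '%s'\n",
              object@labelA, object@labelB))
  cat("  relative differences:\n")
  cat(sprintf("    %s: %.4f\n", names(object@perParameter),
              object@perParameter), sep = "")
  cat(sprintf("  ARD = %.1f%%\n", reportRound(object@ardPercent, 1L)))
})

#' Pairwise ARD matrix
#'
#' Computes the symmetric matrix of ARD percentages for a collection of
#' networks or parameter sets.
#'
#' @param x list of [NetworkParameters-class] and/or
#'   [AnatomicalNetwork-class] objects with unique names.
#' @return symmetric numeric matrix (zero diagonal) with the network
#'   names as dimnames.
#' @examples
#' m <- ardMatrix(referenceParameters())
#' reportRound(m["Pan_troglodytes_forelimb", "Pan_troglodytes_hindlimb"], 1)
#' @export
ardMatrix <- function(x) {
  if (length(x) < 2L)
    .anStop("tooFewNetworksError", "need at least 2 networks to compare")
  params <- lapply(x, function(el) {
    if (is(el, "AnatomicalNetwork")) networkParameters(el) else el
  })
  nm <- vapply(params, networkName, character(1))
  if (anyDuplicated(nm))
    .anStop("duplicateNameError", "duplicate network name(s): %s",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  k <- length(params)
  M <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    v <- ardPercent(ard(params[[i]], params[[j]]))
    M[i, j] <- v
    M[j, i] <- v
  }
  M
}
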