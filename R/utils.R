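# Internal helpers: typed conditions, deterministic ordering, rounding.

# All package errors carry a specific class plus "anatnetError" so callers
# can catch the precise failure (e.g. expect_error(class = "asymmetryError")).
.anStop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "anatnetError")))
}

# C-locale (byte-wise) sorting so canonical node order does not depend on
# the user's collation locale.
.csort <- function(x) sort(x, method = "radix")
.corder <- function(...) order(..., method = "radix")

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves moving away from zero, the
#' convention used for reported percentages and parameter tables (unlike
#' [base::round()], which rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' reportRound(c(8.05, -8.05, 5.348), 1)
#' @export
reportRound <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Run code with a private RNG stream: seeds deterministically, restores the
# caller's .Random.seed afterwards.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
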