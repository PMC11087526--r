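#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with \code{set.seed(seed)} and restores the caller's
#' RNG state afterwards, so seeded operations never disturb surrounding
#' randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a component seed from a global seed
#'
#' A single global seed fans out to per-component seeds via
#' \code{(seed * 7919 + 104729 * index) mod (2^31 - 1)}: deterministic,
#' collision-free across the handful of components, and always a valid
#' 32-bit integer seed.
#'
#' @param seed global integer seed.
#' @param index nonnegative component index.
#' @return derived integer seed.
#' @export
splitSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %% 2147483647)
}

upperTri <- function(m) m[upper.tri(m)]
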