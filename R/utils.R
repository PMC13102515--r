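#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the random number generator seeded to `seed`, then
#' restores whatever RNG state the caller had. All stochastic steps in the
#' package route their randomness through this helper so that a single root
#' seed makes every artifact reproducible.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a root seed
#'
#' Keeps all derived seeds inside the 32-bit integer range.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% .Machine$integer.max)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
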