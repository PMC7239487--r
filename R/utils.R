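#' Derive a child seed from a master seed
#'
#' All stage- and subject-level randomness in the pipeline is seeded with
#' values derived deterministically from one master seed, so that a whole run
#' is a pure function of that seed. The derivation keeps results inside the
#' 32-bit signed integer range R requires of `set.seed()`.
#'
#' @param master integer master seed.
#' @param offset non-negative integer stream offset (stage index, subject
#'   index, ...). Distinct offsets give distinct, reproducible streams.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, offset = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(offset), length(offset) == 1L, offset >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.numeric(master)) %% m)
  # two rounds of a multiplicative congruential step keep streams well separated
  s <- (s * 48271 + as.numeric(offset) + 1) %% m
  s <- (s * 69621 + 11) %% m
  as.integer(s)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
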