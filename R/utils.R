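# Internal helpers shared across modules.

#' Standardize a numeric vector to mean 0, variance 1
#'
#' @param y numeric vector with at least two distinct finite values.
#' @return numeric vector with mean 0 and (sample) variance 1.
#' @keywords internal
standardize <- function(y) {
  s <- stats::sd(y)
  if (!is.finite(s) || s <= 0) {
    stop("cannot standardize a constant or non-finite vector", call. = FALSE)
  }
  (y - mean(y)) / s
}

# Deterministic child-seed derivation: every stage that needs its own RNG
# stream hashes the master seed with a small stage offset, keeping results
# reproducible under one master seed while decoupling the stages.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647L)
}

# Run an expression under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
}
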