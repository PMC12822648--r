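#' Derive a child seed from a base seed and an index path
#'
#' All randomness in the package flows from one integer seed through a
#' hierarchical split (cohort -> subject -> run -> stage). Each level mixes
#' the parent seed with an index using a Lehmer-style multiplicative chain
#' carried out exactly in double precision, so the same `(seed, path)` pair
#' always yields the same child seed on any platform.
#'
#' @param seed integer base seed (non-negative, below 2^31).
#' @param ... integer indices identifying the branch, e.g.
#'   `derive_seed(seed, subject, run)`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed) %% 2147483647
  # one extra fixed step decorrelates (seed) from (seed, 0)
  s <- (s * 48271 + 11) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + (as.numeric(k) %% 65536) * 7919 + 1) %% 2147483647
    s <- (s * 16807 + 3) %% 2147483647
  }
  as.integer(s)
}

# run an expression with a local R RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
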