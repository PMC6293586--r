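# Shared helpers: seed derivation, local RNG scoping, numeric utilities.

#' Derive a child seed from a master seed
#'
#' Child seeds are a pure function of the master seed and an index path
#' (e.g. gene index, then taxon index), so extending a simulation with more
#' genes never changes the genes already simulated. All arithmetic stays
#' below 2^31 so seeds remain valid R integers.
#'
#' @param seed master seed (non-negative integer).
#' @param ... integer indices identifying the consumer, in a fixed order.
#' @return an integer seed in `[1, 2147483646]`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    # 69069 * 2^31 < 2^53: exact in double arithmetic
    s <- (s * 69069 + as.double(k) + 12345) %% 2147483647
  }
  as.integer(s %% 2147483646) + 1L
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)
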