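# Seed-stream derivation. Every stochastic operation draws from its own RNG
# stream derived from (master seed, stream name), so that adding or reordering
# calls elsewhere in a pipeline never changes the numbers an operation produces.

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' The scheme is a stable polynomial hash of the stream name folded into the
#' master seed modulo 2^31 - 1, so it is identical across platforms and R
#' versions and always yields a valid 32-bit integer seed.
#'
#' @param seed Integer master seed.
#' @param stream Character scalar naming the operation/stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stream), length(stream) == 1L, nzchar(stream))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  as.integer(((abs(seed) %% m) * 48271 + h) %% m)
}

#' Evaluate an expression under a derived RNG stream
#'
#' Sets the RNG state from [stream_seed()] for the duration of `expr` and
#' restores the caller's state afterwards, so surrounding code is unaffected.
#'
#' @param seed Integer master seed.
#' @param stream Stream name (character).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_stream <- function(seed, stream, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  expr
}
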