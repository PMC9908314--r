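#' Derive a reproducible substream seed from a master seed
#'
#' Mixes a master seed with one or more non-negative integer indices
#' (cell index, protocol index, trial index, ...) into a new seed in
#' `[0, 2^31 - 2]`. The mixing is a Lehmer-style multiplicative hash, so a
#' given `(master, indices)` combination always yields the same substream
#' seed regardless of how many other substreams are drawn. This is what lets
#' the simulator keep early trials bit-identical when later trials are added.
#'
#' @param master Integer master seed.
#' @param ... Non-negative integer indices identifying the substream.
#' @return A single integer seed.
#' @export
#' @examples
#' mix_seed(42, 3, 1, 2)
mix_seed <- function(master, ...) {
  idx <- c(...)
  stopifnot(length(master) == 1, is.finite(master))
  s <- as.double(abs(as.integer(master)) %% 2147483647)
  for (k in idx) {
    stopifnot(is.finite(k), k >= 0)
    # 48271 * (2^31 - 2) < 2^53: exact in double arithmetic
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

# run an expression with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_user <- function(...) {
  stop(paste0(...), call. = FALSE)
}
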