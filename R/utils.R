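#' @importFrom rlang abort warn
#' @importFrom tibble tibble as_tibble
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# With seed = NULL the ambient RNG stream is used (and advanced).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Components (pool generation, group allocation, interval sampling, the
#' optimizer, Monte-Carlo hypervolume) each draw their own seed from the master
#' seed with a fixed linear-congruential hash, so they can be re-run in
#' isolation while remaining jointly reproducible. Results stay below 2^31.
#'
#' @param seed Master seed (non-negative integer).
#' @param k Stream index (non-negative integer).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(seed, k = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k))
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m) + 1
  for (i in seq_len(k + 1)) x <- (x * 48271) %% m
  as.integer(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
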