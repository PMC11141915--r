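#' @keywords internal
"_PACKAGE"

## RNG helpers ---------------------------------------------------------------

#' Derive a child seed from a master seed and a stream label
#'
#' A small polynomial string hash folded with the master seed, reduced modulo
#' 2^31 - 1 so the result is always a valid R integer seed. Streams labelled by
#' stable identifiers (region ids, table names) are therefore independent of
#' how many other streams exist: adding a region to a scenario never perturbs
#' the draws of existing regions.
#'
#' @param seed master integer seed
#' @param label character stream label
#' @return integer seed in `[0, 2^31 - 2]`
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label))
  m <- 2147483647              # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## misc ----------------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

# weighted mean that tolerates zero total weight
wmean <- function(x, w) {
  if (sum(w) <= 0) return(NA_real_)
  sum(x * w) / sum(w)
}
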