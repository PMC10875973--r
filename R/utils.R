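# Internal helpers shared across modules.

#' @keywords internal
round_half_away <- function(x) {
  # base::round() rounds half to even; reported foci conventions need a fixed
  # half-away-from-zero rule so that e.g. 2.5 -> 3 and -2.5 -> -3.
  sign(x) * floor(abs(x) + 0.5)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-module seed fan-out: one user seed per run, split into
# independent substreams by a counter so modules never share a stream.
#' @keywords internal
derive_seed <- function(seed, counter) {
  ((as.integer(seed) %% 1000000L) * 2047L + 97L * as.integer(counter)) %% 2147483647L
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
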