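# Reproducibility helpers.  All stochastic stages draw from substreams
# derived deterministically from one master seed, so a run is a pure
# function of its configuration.

#' Derive a substream seed from a master seed and a key
#'
#' Deterministically maps `(seed, key)` to an integer in `[0, 2^31 - 2]`
#' usable with [set.seed()].  Keys are arbitrary strings (a wavelength,
#' a replicate label, a stage name); distinct keys give distinct,
#' uncorrelated-looking streams.
#'
#' @param seed master seed, a single non-negative integer.
#' @param key character or numeric scalar labelling the substream.
#' @return a single integer seed.
#' @export
#' @examples
#' substream_seed(1, "380")
#' substream_seed(1, "390")
substream_seed <- function(seed, key) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    abort_config("master seed must be a single non-negative number")
  # polynomial rolling hash over the key bytes, modulo a Mersenne prime;
  # plain double arithmetic stays exact below 2^53
  m <- 2147483647
  h <- as.numeric(seed) %% m
  bytes <- utf8ToInt(paste0(as.character(key), "|"))
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer(h)
}

# Run `expr` under a given seed without disturbing the caller's RNG state.
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
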