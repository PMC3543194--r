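# Internal helpers.

# Evaluate `code` without disturbing the caller's RNG stream.
with_preserved_seed <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

# Deterministic child seed from a master seed and integer tags; stays
# within the 32-bit signed range.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (t in tags) {
    h <- (h * 48271 + as.double(t) + 1) %% 2147483647
  }
  as.integer(h)
}
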