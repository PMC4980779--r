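# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library calls never disturb the user's random stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a reproducible sub-seed from a base seed and a stream index,
# staying inside the 32-bit signed integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647)
}
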