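# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, staying within
# the 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(stream)) %%
               2147483647)
}

# Equal-tailed percentile interval plus median, as a named vector.
ci_summary <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  q <- stats::quantile(x, c(a, 0.5, 1 - a), names = FALSE, type = 7)
  c(low = q[1L], median = q[2L], high = q[3L])
}
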