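# Seed plumbing. Every stochastic operation takes one integer master seed and
# derives independent substreams by hashing (seed, stream id) into a 31-bit
# integer, so per-patient draws do not depend on evaluation order.

# SplitMix-style integer hash restricted to 31-bit arithmetic (R integers).
mix_seed <- function(seed, ...) {
  ids <- c(seed, unlist(list(...), use.names = FALSE))
  h <- 0L
  for (x in ids) {
    x <- as.integer(x)
    h <- bitwXor(h, x)
    # 31-bit multiplicative mixing; keep everything in [0, 2^31)
    h <- as.integer((as.double(h) * 2654435761 + 104729) %% 2147483647)
    h <- bitwXor(h, bitwShiftR(h, 13L))
    h <- as.integer((as.double(bitwAnd(h, 2147483647L)) * 97 + 17) %% 2147483647)
  }
  if (h < 0L) h <- -h
  if (h == 0L) h <- 1L
  h
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# global RNG state is untouched.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
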