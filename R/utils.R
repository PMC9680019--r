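# internal helpers shared across modules

# evaluate quadratic k0 + k1*t + k2*t^2 given coefficient vector of length 3
poly2 <- function(k, t) k[1] + k[2] * t + k[3] * t^2

# run code with a private RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs a
# user's simulation stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

# derive independent sub-seeds (< 2^31) from one master seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
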