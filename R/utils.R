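# Run code under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-participant substream seed derived from a master seed,
# independent of generation order. Kept below 2^31 - 1.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 2246822519) %%
               2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Mean-one lognormal multiplier with coefficient of variation cv.
lognormal_sigma <- function(cv) sqrt(log1p(cv^2))
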