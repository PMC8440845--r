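# Named RNG substreams: every simulated unit (subject x epoch x assay) draws
# from a seed derived deterministically from the cohort seed, so regenerating
# one session reproduces the same numbers regardless of generation order.

# Deterministic integer mix of a base seed and a vector of stream indices.
# Splitmix-style multiply/xor folding, kept in double precision below 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
    h <- (h * 69621) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a local seed without disturbing the caller's RNG state.
with_stream <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Multiplicative lognormal noise with unit mean and given coefficient of
# variation; cv = 0 returns exact 1s (supports noise-free closed-form tests).
lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sig2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -sig2 / 2, sdlog = sqrt(sig2))
}
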