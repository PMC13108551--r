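# Internal helpers shared across modules.

# Derive a stage seed from a root seed, staying inside 32-bit range.
derive_seed <- function(seed, stage) {
  (as.double(seed) * 48271 + stage * 16807) %% 2147483647
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Standardize to mean 0, SD 1; constants map to 0.
zscale <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# FNV-1a hash of a character representation; used to stamp pipeline outputs
# with the configuration they came from.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

# Small-sample corrected AIC for an lm fit.
aicc <- function(fit) {
  k <- length(stats::coef(fit)) + 1          # + sigma
  n <- stats::nobs(fit)
  stats::AIC(fit) + 2 * k * (k + 1) / max(n - k - 1, 1)
}
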