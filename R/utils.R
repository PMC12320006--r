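# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.  seed = NULL means "use the current stream".
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)  # materialise .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; stays well below .Machine$integer.max.
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 1000003L)
  for (k in idx) s <- (s * 7919 + as.double(k) * 104729 + 17) %% 2147483647
  as.integer(s)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Population-SD z-scoring of a numeric vector.
zscorePop <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) return(rep(NaN, length(x)))
  (x - mu) / s
}
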