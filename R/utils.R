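# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stopf("'%s' must be a single number in [%s, %s]", name, lo, hi)
  invisible(x)
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards, so library functions never disturb a user's stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stable 31-bit hash of (seed, label): used to derive independent,
# generation-order-free RNG streams (e.g. one per simulated gene).
# Plain iterated polynomial hash mod the Mersenne prime 2^31 - 1; all
# arithmetic stays below 2^53 so doubles are exact.
hash_seed <- function(seed, label) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(paste0(label))) h <- (h * 131 + b) %% m
  as.integer((h %% (m - 1)) + 1)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
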