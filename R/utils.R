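# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

assert_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_domain(name, " must be a single positive finite number")
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_domain(name, " must be TRUE or FALSE")
  invisible(x)
}

# Counter-based child seed derivation (Lehmer-style mixing, modulus 2^31-1).
# Deterministic in (seed, i), order-independent, always in [1, 2^31 - 2] so it
# is a valid value for set.seed() on 32-bit R integers.
child_seed <- function(seed, i) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m + m) %% m
  x <- (s * 48271 + (as.numeric(i) %% m) * 104729 + 12345) %% m
  as.integer(if (x < 1) x + 1 else x)
}

# Stable fingerprint of a character scalar (polynomial rolling hash modulo a
# Mersenne prime); used for provenance config hashes, not cryptography.
config_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  m <- 2147483647
  h <- 0
  for (b in bytes) h <- (h * 131 + b + 1) %% m
  sprintf("%08x", as.integer(h))
}

# Linear least squares y ~ 1 + x returning slope, intercept, r-squared.
# Bare-metal version of lm() used in per-track fitting hot loops.
ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  dx <- x - mx
  ssx <- sum(dx^2)
  if (ssx <= 0) return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_))
  slope <- sum(dx * (y - my)) / ssx
  intercept <- my - slope * mx
  ssres <- sum((y - intercept - slope * x)^2)
  sstot <- sum((y - my)^2)
  r2 <- if (sstot > 0) 1 - ssres / sstot else NA_real_
  list(slope = slope, intercept = intercept, r2 = r2)
}
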