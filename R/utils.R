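# small internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic derivation of sub-seeds from one master integer seed.
# Simple multiplicative mixing mod a Mersenne prime; keeps results < 2^31
# so they are valid R integer seeds. All phantom randomness flows through
# this so that a single seed reproduces every fixture bit-identically.
derive_seed <- function(seed, ...) {
  parts <- c(as.double(seed), as.double(unlist(list(...))))
  m <- 2147483647 # 2^31 - 1
  x <- 0
  for (p in parts) {
    x <- (x * 69069 + (p %% m) * 40503 + 12345) %% m
  }
  as.integer(x %% (m - 1) + 1)
}

# closed-form simple linear regression; returns intercept, slope, r.squared
# (used in the log-log spectral fit, called once per A-scan per layer)
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  dx <- x - mx
  sxx <- sum(dx^2)
  if (sxx <= 0) return(list(intercept = my, slope = 0, r_squared = NA_real_))
  slope <- sum(dx * (y - my)) / sxx
  intercept <- my - slope * mx
  fitted <- intercept + slope * x
  sst <- sum((y - my)^2)
  r2 <- if (sst > 0) 1 - sum((y - fitted)^2) / sst else NA_real_
  list(intercept = intercept, slope = slope, r_squared = r2)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)
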