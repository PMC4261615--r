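# Independent oracles used across the suite. Each is a deliberately naive
# implementation kept separate from the package's computation path.

# Exact fractional Brownian motion by Davies-Harte circulant embedding of
# fractional Gaussian noise, then cumulative summation. Validated by the
# self-similarity law Var(B_t) = t^(2H) (see test-fractal.R).
rfbm <- function(n, H) {
  m <- 2 * n
  k <- 0:(m / 2)
  r <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  rc <- c(r, rev(r[2:(m / 2)]))
  lam <- Re(stats::fft(rc))
  lam[lam < 0] <- 0
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  fgn <- Re(stats::fft(sqrt(lam / (2 * m)) * z))[1:n] * sqrt(2)
  cumsum(fgn)
}

# Brute-force DFT periodogram (no FFT), positive bins below Nyquist.
brute_periodogram <- function(x) {
  n <- length(x)
  kmax <- ceiling(n / 2) - 1
  vapply(seq_len(kmax), function(k) {
    t <- 0:(n - 1)
    re <- sum(x * cos(-2 * pi * k * t / n))
    im <- sum(x * sin(-2 * pi * k * t / n))
    (re^2 + im^2) / n
  }, numeric(1))
}

# AUROC by explicit pair counting with weight 1/2 at ties; direction "low"
# means low values call disease.
brute_auroc <- function(cases, controls, direction = "low") {
  s <- if (direction == "low") -1 else 1
  tot <- 0
  for (x in cases) {
    for (y in controls) {
      tot <- tot + if (s * x > s * y) 1 else if (s * x == s * y) 0.5 else 0
    }
  }
  tot / (length(cases) * length(controls))
}

# One-way ANOVA F from explicit sums of squares.
brute_anova_f <- function(values, group) {
  group <- factor(group)
  gm <- mean(values)
  means <- tapply(values, group, mean)
  ns <- tapply(values, group, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[group])^2)
  k <- nlevels(group)
  (ssb / (k - 1)) / (ssw / (length(values) - k))
}

# A small, fast phantom geometry used where the full 512 x 1024 default is
# not the quantity under test.
small_spec <- function(...) {
  phantom_spec(n_ascans = 64, n_depth = 320, foveal_pit_depth = 40,
               foveal_pit_width = 300, ...)
}
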