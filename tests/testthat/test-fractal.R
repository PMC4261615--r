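# Spectral-exponent / fractal-dimension estimation.

test_that("profile extraction follows the half-open ceiling convention", {
  px <- matrix(seq_len(40 * 4), nrow = 40, ncol = 4)
  img <- bscan(px / max(px), 2, 10)
  mkseg <- function(u, l) {
    rows <- matrix(seq(2, 38, length.out = 8), nrow = 8, ncol = 4)
    rows[2, ] <- u; rows[3, ] <- l
    rows[1, ] <- pmin(rows[1, ], u)
    for (b in 4:8) rows[b, ] <- pmax(rows[b, ], l)
    layer_seg(rows)
  }
  # integer boundaries 10 and 20: 10 pixels, depth interval [10, 20)
  p <- extract_profile(img, mkseg(10, 20), "GCL+IPL", 2)
  expect_equal(p$n, 10)
  expect_equal(p$values, img$pixels[11:20, 2])
  # fractional boundaries shift by the ceiling rule
  p <- extract_profile(img, mkseg(10.4, 20.4), "GCL+IPL", 1)
  expect_equal(p$n, 10)
  expect_equal(p$values, img$pixels[12:21, 1])
  # equal boundaries: degenerate empty profile
  p <- extract_profile(img, mkseg(15, 15), "GCL+IPL", 3)
  expect_equal(p$n, 0)
})

test_that("periodogram matches a brute-force DFT and satisfies Parseval", {
  set.seed(77)
  for (rep in 1:5) {
    x <- stats::rnorm(32)
    sp <- power_spectrum(x, detrend = FALSE)
    expect_equal(sp$power, brute_periodogram(x), tolerance = 1e-10)
    expect_equal(sp$frequency, (1:15) / 32)
    # Parseval: 2 * sum(returned) + DC + Nyquist = sum(x^2)
    xc <- x - mean(x)
    spc <- power_spectrum(xc, detrend = FALSE)
    nyq <- Mod(stats::fft(xc))[17]^2 / 32
    expect_equal(2 * sum(spc$power) + nyq, sum(xc^2), tolerance = 1e-10)
  }
})

test_that("pure tones and constants behave as stated", {
  n <- 64
  x <- cos(2 * pi * 5 * (0:(n - 1)) / n)
  sp <- power_spectrum(x, detrend = FALSE)
  expect_equal(which.max(sp$power), 5)
  expect_lt(sum(sp$power[-5]) / sp$power[5], 1e-20)

  const <- power_spectrum(rep(3, 16), detrend = TRUE)
  expect_true(all(const$power < 1e-25))
  expect_error(power_spectrum(rep(1, 5)), "too short")
})

test_that("exactly collinear log-log spectra are fitted to machine precision", {
  for (beta in c(1.2, 1.5, 2.0, 2.6)) {
    sp <- structure(list(frequency = (1:40) / 128,
                         power = ((1:40) / 128)^(-beta), n = 128),
                    class = "power_spectrum")
    fit <- fit_beta(sp)
    expect_lt(abs(fit$beta - beta), 1e-10)
    expect_equal(fit$fd, (5 - fit$beta) / 2)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
    expect_true(fit$valid)
  }
})

test_that("flat spectra give beta 0, FD 2.5, flagged invalid", {
  sp <- structure(list(frequency = (1:20) / 64, power = rep(2, 20), n = 64),
                  class = "power_spectrum")
  fit <- fit_beta(sp)
  expect_equal(fit$beta, 0, tolerance = 1e-12)
  expect_equal(fit$fd, 2.5)
  expect_false(fit$valid)
})

test_that("zero-power bins are dropped; too few bins invalidate the fit", {
  sp <- structure(list(frequency = (1:6) / 32,
                       power = c(1, 0, 1 / 9, 0, 1 / 25, 0), n = 32),
                  class = "power_spectrum")
  fit <- fit_beta(sp, min_points = 3)
  expect_equal(fit$n_fit_points, 3)
  expect_lt(abs(fit$beta - 2), 1e-10) # remaining bins are exactly w^-2
  fit2 <- fit_beta(sp, min_points = 4)
  expect_false(fit2$valid)
  expect_match(fit2$reason, "usable spectral bins")
})

test_that("fd = (5 - beta)/2 identity and scale invariance hold generally", {
  set.seed(88)
  for (rep in 1:20) {
    x <- 1 + fractal_texture(128, runif(1, 1.2, 2.8), sd = 0.3)
    f1 <- fit_beta(power_spectrum(x))
    expect_equal(f1$fd, (5 - f1$beta) / 2)
    f2 <- fit_beta(power_spectrum(x * runif(1, 0.01, 100)))
    expect_equal(f2$beta, f1$beta, tolerance = 1e-10)
  }
})

test_that("the estimator recovers the Hurst law on true fractional Brownian motion", {
  # independent oracle: Davies-Harte fBm, FD = 2 - H; first check the
  # generator itself via the self-similarity law Var(B_t) = t^(2H)
  set.seed(99)
  B <- replicate(1500, rfbm(64, 0.8)[c(16, 64)])
  expect_equal(stats::var(B[1, ]) / 16^1.6, 1, tolerance = 0.1)
  expect_equal(stats::var(B[2, ]) / 64^1.6, 1, tolerance = 0.1)

  # H = 0.8 => beta = 2.6, FD = 1.2; Hann taper plus a low-frequency band
  # control the leakage that otherwise caps the measurable slope near 2
  fds <- replicate(100, {
    fit_beta(power_spectrum(rfbm(4096, 0.8), taper = TRUE),
             band = c(0, 0.125))$fd
  })
  expect_lt(abs(mean(fds) - 1.20), 0.10)
})

test_that("layer_fd recovers planted truth and accounts for every A-scan", {
  fdv <- c(RNFL = 1.74, `GCL+IPL` = 1.58, INL = 1.78, OPL = 1.51,
           `ONL+IS` = 1.78, OS = 1.70, RPE = 1.68)
  ph <- generate_bscan(phantom_spec(layer_fd = fdv, seed = 11))
  s <- layer_fd(ph$image, ph$truth$boundaries, "GCL+IPL")
  expect_lt(abs(s$mean_fd - 1.58), 0.05)
  expect_equal(s$n_used + sum(s$exclusions), s$n_ascans)

  # masking 10% of columns moves the mean by less than the seed-to-seed SD
  seed_means <- vapply(1:6, function(sd) {
    p <- generate_bscan(phantom_spec(layer_fd = fdv, seed = 70 + sd))
    layer_fd(p$image, p$truth$boundaries, "GCL+IPL")$mean_fd
  }, numeric(1))
  set.seed(5)
  cols <- sort(sample(512, 51))
  iv <- lapply(cols, function(cc) c(cc, cc + 1))
  masked <- layer_fd(ph$image, ph$truth$boundaries, "GCL+IPL",
                     mask = shadow_mask(iv, 512))
  expect_equal(sum(masked$exclusions["shadow"]), 51)
  expect_lt(abs(masked$mean_fd - s$mean_fd), stats::sd(seed_means))

  # everything masked: missing value with a reason, not a crash
  all_masked <- layer_fd(ph$image, ph$truth$boundaries, "GCL+IPL",
                         mask = shadow_mask(list(c(1, 513)), 512))
  expect_true(is.na(all_masked$mean_fd))
  expect_equal(all_masked$reason, "no valid A-scans")
})

test_that("profiles thinner than the minimum are excluded, never padded", {
  ph <- generate_bscan(small_spec(seed = 31))
  # RPE ~ 6 px at this geometry: everything excluded as too short
  s <- layer_fd(ph$image, ph$truth$boundaries, "RPE", min_profile = 8)
  expect_true(is.na(s$mean_fd))
  expect_equal(unname(s$exclusions["too_short"]), s$n_ascans)
})

test_that("eye-level FD is the unweighted mean of per-scan means", {
  expect_equal(eye_fd(list(c(`GCL+IPL` = 1.6), c(`GCL+IPL` = 1.7))),
               c(`GCL+IPL` = 1.65))
  expect_equal(eye_fd(list(c(A = 1.6, B = NA), c(A = 1.7, B = NA))),
               c(A = 1.65, B = NA_real_))
  sp <- small_spec(seed = 33)
  eye <- make_eye(sp, n_scans = 6)
  per_scan <- lapply(eye, function(sc)
    list(layer_fd(sc$image, sc$truth$boundaries, "GCL+IPL")))
  est <- eye_fd(per_scan)["GCL+IPL"]
  expect_lt(abs(est - sp$layer_fd["GCL+IPL"]), 0.03)
})
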