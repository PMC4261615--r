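# Phantom generator: determinism, geometry, planted truth.

test_that("identical spec and seed reproduce the image bit-identically", {
  sp <- small_spec(seed = 42, speckle_looks = 4,
                   shadow_columns = list(c(10, 5)))
  a <- generate_bscan(sp)
  b <- generate_bscan(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$boundaries$rows, b$truth$boundaries$rows)
  c <- generate_bscan(small_spec(seed = 43, speckle_looks = 4,
                                 shadow_columns = list(c(10, 5))))
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("noise-free layer bands average to the planted reflectivity", {
  sp <- small_spec(seed = 7) # speckle disabled by default
  ph <- generate_bscan(sp)
  for (lay in c("RNFL", "GCL+IPL", "ONL+IS", "RPE")) {
    vals <- unlist(lapply(seq_len(sp$n_ascans), function(a) {
      extract_profile(ph$image, ph$truth$boundaries, lay, a)$values
    }))
    # texture fluctuation has mean zero by construction (clipping at 0 can
    # only nudge the mean up by a negligible amount at sd 0.3)
    expect_equal(mean(vals), unname(sp$layer_reflectivity[lay]),
                 tolerance = 0.02)
  }
})

test_that("planted truth satisfies its invariants", {
  for (seed in 1:5) {
    sp <- small_spec(seed = seed)
    ph <- generate_bscan(sp)
    expect_true(all(apply(ph$truth$boundaries$rows, 2, diff) >= 0))
    expect_identical(ph$truth$shadow_columns, integer(0))
    expect_equal(ph$truth$layer_fd, (5 - ph$truth$layer_beta) / 2)
    expect_true(all(ph$truth$layer_fd > 1 & ph$truth$layer_fd < 2))
    expect_true(all(ph$image$pixels >= 0))
  }
})

test_that("layer geometry that does not fit the depth range is rejected", {
  expect_error(phantom_spec(n_depth = 100, axial_pitch = 2),
               "geometry overflow")
})

test_that("spectral shaping plants the requested power-law exponent", {
  # averaged periodogram over many realizations must regress to slope -beta
  set.seed(301)
  for (beta in c(1.4, 2.2)) {
    P <- rowMeans(replicate(150, brute_periodogram(
      fractal_texture(64, beta, sd = 1))))
    k <- seq_along(P)
    slope <- stats::coef(stats::lm(log(P) ~ log(k)))[2]
    expect_lt(abs(slope + beta), 0.1)
  }
})

test_that("recovered mean FD matches a planted GCL+IPL exponent", {
  # beta = 1.64 <=> FD 1.68; periodogram-regression mean over 512 A-scans
  # at the default geometry must land within the sampling tolerance
  fdv <- default <- c(RNFL = 1.74, `GCL+IPL` = 1.68, INL = 1.78,
                      OPL = 1.51, `ONL+IS` = 1.78, OS = 1.70, RPE = 1.68)
  means <- vapply(1:3, function(s) {
    ph <- generate_bscan(phantom_spec(layer_fd = fdv, seed = 60 + s))
    layer_fd(ph$image, ph$truth$boundaries, "GCL+IPL")$mean_fd
  }, numeric(1))
  expect_lt(abs(mean(means) - 1.68), 0.05)
})

test_that("make_eye returns replicate scans sharing the planted truth", {
  sp <- small_spec(seed = 9)
  eye <- make_eye(sp, n_scans = 6)
  expect_length(eye, 6)
  fds <- lapply(eye, function(s) s$truth$layer_fd)
  for (f in fds[-1]) expect_identical(f, fds[[1]])
  expect_length(make_eye(sp, n_scans = 1), 1)
  # replicates differ in their realizations
  expect_false(identical(eye[[1]]$image$pixels, eye[[2]]$image$pixels))
})

test_that("averaging scans within an eye shrinks the FD spread across seeds", {
  single <- numeric(12); averaged <- numeric(12)
  for (s in seq_len(12)) {
    sp <- small_spec(seed = 7000 + s)
    eye <- make_eye(sp, n_scans = 4)
    per_scan <- vapply(eye, function(sc)
      layer_fd(sc$image, sc$truth$boundaries, "GCL+IPL")$mean_fd, numeric(1))
    single[s] <- per_scan[1]
    averaged[s] <- mean(per_scan)
  }
  expect_lt(stats::sd(averaged), stats::sd(single))
})

test_that("cohort generation honors jitter settings and group symmetry", {
  h <- small_spec(seed = 11)
  dfd <- h$layer_fd; dfd["GCL+IPL"] <- 1.58
  d <- small_spec(layer_fd = dfd, seed = 11)

  co0 <- make_cohort(h, d, 5, 5, between_eye_sd = 0)
  hrows <- co0$study[co0$study$group == "healthy", ]
  expect_true(all(apply(hrows[, -(1:2)], 2, function(v) diff(range(v)) == 0)))

  co <- make_cohort(h, d, 74, 43, between_eye_sd = list(fd = 0.01),
                    between_eye_sd_diseased = list(fd = 0.05))
  expect_equal(nrow(co$study), 117)
  x <- co$study$`fd_GCL+IPL`
  g <- co$study$group
  a <- auroc(x[g == "MDR"], x[g == "healthy"], direction = "low")
  # binormal closed form: Phi(0.10 / sqrt(0.01^2 + 0.05^2)) ~ 0.975
  expect_lt(abs(a - stats::pnorm(0.10 / sqrt(0.01^2 + 0.05^2))), 0.04)
  # swapping which group is called diseased mirrors the AUROC
  a_sw <- auroc(x[g == "healthy"], x[g == "MDR"], direction = "low")
  expect_equal(a_sw, 1 - a)
})
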