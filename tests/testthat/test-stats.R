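# ANOVA, Newman-Keuls, ROC/AUROC, cutoffs, layer comparison.

test_that("one-way ANOVA matches brute-force sums of squares and t^2", {
  set.seed(51)
  v <- c(rnorm(5, 0), rnorm(5, 1), rnorm(5, 2))
  g <- rep(c("a", "b", "c"), each = 5)
  av <- anova_oneway(v, g)
  expect_equal(av$f, brute_anova_f(v, g), tolerance = 1e-10)

  # two groups: F equals the square of the pooled two-sample t statistic
  v2 <- c(rnorm(8, 0), rnorm(10, 0.7)); g2 <- rep(c("a", "b"), c(8, 10))
  tt <- stats::t.test(v2[g2 == "a"], v2[g2 == "b"], var.equal = TRUE)
  expect_equal(anova_oneway(v2, g2)$f, unname(tt$statistic)^2,
               tolerance = 1e-10)

  # identical constants: F = 0; unequal constants: degenerate flag
  expect_equal(anova_oneway(rep(5, 10), rep(c("a", "b"), 5))$f, 0)
  dg <- anova_oneway(rep(c(1, 2), each = 5), rep(c("a", "b"), each = 5))
  expect_true(dg$degenerate)
  expect_lt(dg$p, 1e-300)
})

test_that("Newman-Keuls two-group decision equals the pooled t-test", {
  set.seed(52)
  for (alpha in c(0.05, 0.01)) {
    for (rep in 1:20) {
      v <- c(rnorm(7, 0), rnorm(9, runif(1, 0, 1.2)))
      g <- rep(c("a", "b"), c(7, 9))
      nk <- newman_keuls(v, g, alpha = alpha)
      tt <- stats::t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
      expect_identical(nk$significant[1], tt$p.value < alpha)
      # q = t * sqrt(2) identity
      expect_equal(nk$q[1], abs(unname(tt$statistic)) * sqrt(2),
                   tolerance = 1e-10)
    }
  }
})

test_that("Newman-Keuls step-down logic on a 0/0/5 three-group design", {
  set.seed(53)
  v <- c(rnorm(20, 0), rnorm(20, 0), rnorm(20, 5))
  g <- rep(c("a", "b", "c"), each = 20)
  nk <- newman_keuls(v, g, alpha = 0.05)
  row <- function(g1, g2) nk[(nk$group1 == g1 & nk$group2 == g2) |
                               (nk$group1 == g2 & nk$group2 == g1), ]
  expect_true(row("a", "c")$significant)
  expect_true(row("b", "c")$significant)
  expect_false(row("a", "b")$significant)
  # q values match the direct studentized-range evaluation
  msw <- attr(nk, "ms_within"); df <- attr(nk, "df")
  means <- tapply(v, g, mean)
  q_ac <- abs(means["a"] - means["c"]) / sqrt(msw / 20)
  expect_equal(row("a", "c")$q, unname(q_ac), tolerance = 1e-10)
  expect_equal(row("a", "c")$p,
               stats::ptukey(unname(q_ac), row("a", "c")$span, df,
                             lower.tail = FALSE), tolerance = 1e-12)
  # identical-mean groups: nothing rejected
  v0 <- rep(c(1, 2, 3), each = 12)
  nk0 <- newman_keuls(v0, rep(c("a", "b", "c"), 12))
  expect_false(any(nk0$significant))
})

test_that("non-significant outer spans block nested comparisons", {
  # engineered groups with exact means 0 / 0.98 / 1.00 and exact pooled
  # SE_q = 1/3: the outer span's q = 3.0 sits below the span-3 critical
  # value (~3.41 at df = 45) while the 0-vs-0.98 pair's q = 2.94 exceeds
  # the span-2 critical value (~2.85) and would be "significant" if it
  # were tested in isolation -- step-down logic must block it
  set.seed(64)
  n <- 16
  mk <- function(m) {
    z <- rnorm(n); z <- (z - mean(z)) / sd(z)
    m + sqrt(16 / 9) * z # exact mean m, exact variance 16/9
  }
  v <- c(mk(0), mk(0.98), mk(1.0))
  g <- rep(c("a", "b", "c"), each = n)
  df <- 3 * n - 3
  stopifnot(stats::qtukey(0.95, 3, df) > 3.0,
            stats::qtukey(0.95, 2, df) < 2.94)
  nk <- newman_keuls(v, g, alpha = 0.05)
  expect_false(any(nk$significant))
  inner <- nk[nk$span == 2, ]
  expect_true(all(inner$blocked))
  # and the blocked flag only ever forces non-significance
  expect_true(all(!nk$significant[nk$blocked]))
})

test_that("AUROC equals brute-force pair counting with half ties", {
  expect_equal(auroc(c(2, 3, 4), c(1, 2, 3), direction = "high"), 7 / 9)
  expect_equal(auroc(c(2, 3, 4), c(1, 2, 3), direction = "low"), 2 / 9)
  set.seed(54)
  for (rep in 1:60) {
    cases <- sample(1:8, sample(2:10, 1), replace = TRUE)
    controls <- sample(1:8, sample(2:10, 1), replace = TRUE)
    dir <- sample(c("low", "high"), 1)
    expect_equal(auroc(cases, controls, dir),
                 brute_auroc(cases, controls, dir), tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone transforms", {
  set.seed(55)
  cases <- rnorm(15, 1); controls <- rnorm(20)
  a <- auroc(cases, controls, "high")
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) stats::plogis(x))) {
    expect_equal(auroc(f(cases), f(controls), "high"), a)
  }
  # reversing direction mirrors the area
  expect_equal(auroc(cases, controls, "low"), 1 - a)
})

test_that("AUROC agrees with an established ROC implementation", {
  set.seed(56)
  x <- c(rnorm(25, 1.58, 0.05), rnorm(30, 1.68, 0.01))
  lab <- rep(c(1, 0), c(25, 30))
  a <- auroc(x[lab == 1], x[lab == 0], direction = "low")
  pr <- pROC::roc(lab, x, direction = ">", quiet = TRUE)
  expect_equal(a, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("ROC curves pass the endpoints implied by separation", {
  perfect <- roc_curve(c(1, 2), c(5, 6), direction = "low")
  expect_equal(attr(perfect, "auroc"), 1)
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
  same <- roc_curve(c(1, 2, 3), c(1, 2, 3), direction = "low")
  expect_equal(attr(same, "auroc"), 0.5)
  expect_error(roc_curve(numeric(0), 1:3), "non-empty")
})

test_that("Hanley-McNeil SE matches the closed form and shrinks with n", {
  expect_equal(auroc_se(1, 10, 10), 0)
  a <- 0.5; n <- 10
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  manual <- sqrt((a * (1 - a) + (n - 1) * (q1 - a^2) + (n - 1) *
                    (q2 - a^2)) / (n * n))
  expect_equal(auroc_se(0.5, 10, 10), manual, tolerance = 1e-14)
  expect_lt(auroc_se(0.8, 50, 60), auroc_se(0.8, 20, 25))
})

test_that("mean-minus-2SD cutoff reproduces the printed threshold", {
  # healthy GCL+IPL FD 1.68 +/- 0.01, lower in disease -> cutoff 1.66
  set.seed(57)
  z <- rnorm(74); z <- (z - mean(z)) / sd(z)
  healthy <- 1.68 + 0.01 * z
  z2 <- rnorm(43); z2 <- (z2 - mean(z2)) / sd(z2)
  cases <- 1.58 + 0.05 * z2
  rr <- select_cutoff(cases, healthy, rule = "mean_minus_2sd",
                      direction = "low")
  expect_equal(rr$cutoff, 1.66, tolerance = 1e-12)
  expect_equal(rr$sensitivity, mean(cases <= 1.66))
  # PLR formula: sens 0.98, spec 0.88 -> 8.17
  expect_equal(0.98 / (1 - 0.88), 8.1666667, tolerance = 1e-6)
  # perfect specificity flags an infinite PLR
  rr2 <- select_cutoff(c(1, 1.1), c(5, 6, 7), rule = "youden",
                       direction = "low")
  expect_true(rr2$plr_infinite)
  expect_identical(rr2$plr, Inf)
})

test_that("youden cutoff maximizes sensitivity + specificity", {
  cases <- c(1, 2, 2, 3); controls <- c(3, 4, 5, 5)
  rr <- select_cutoff(cases, controls, rule = "youden", direction = "low")
  cand <- sort(unique(c(cases, controls)))
  j <- vapply(cand, function(t) mean(cases <= t) + mean(controls > t) - 1,
              numeric(1))
  expect_equal(rr$sensitivity + rr$specificity - 1, max(j))
  # zero healthy SD degenerates mean-minus-2SD to the mean, flagged
  rr3 <- select_cutoff(c(0, 1), c(2, 2, 2), rule = "mean_minus_2sd",
                       direction = "low")
  expect_true(rr3$degenerate_sd)
  expect_equal(rr3$cutoff, 2)
})

test_that("layer comparison ranks the planted discriminator first", {
  h <- small_spec(seed = 61)
  dfd <- h$layer_fd; dfd["GCL+IPL"] <- 1.58
  d <- small_spec(layer_fd = dfd, seed = 61)
  co <- make_cohort(h, d, 20, 20, between_eye_sd = list(fd = 0.01),
                    between_eye_sd_diseased = list(fd = 0.05))
  cmp <- compare_layers(co$study)
  expect_s3_class(cmp, "layer_comparison")
  expect_equal(nrow(cmp), 21) # 7 layers x 3 features
  top <- cmp[which.max(cmp$auroc), ]
  expect_equal(top$layer, "GCL+IPL")
  expect_equal(top$feature, "fd")
  expect_true(top$significant)
})

test_that("label permutation centers the AUROC at one half", {
  set.seed(62)
  study <- data.frame(eye_id = sprintf("e%02d", 1:40),
                      group = rep(c("healthy", "MDR"), each = 20),
                      fd_RNFL = rnorm(40, 1.7, 0.05),
                      check.names = FALSE)
  as <- replicate(200, {
    st <- study
    st$group <- sample(st$group)
    compare_layers(st, features = "fd")$auroc
  })
  expect_lt(abs(mean(as) - 0.5), 0.03)
})

test_that("identically distributed groups rarely clear the 0.001 threshold", {
  set.seed(63)
  n_sig <- replicate(60, {
    study <- data.frame(eye_id = sprintf("e%02d", 1:40),
                        group = rep(c("healthy", "MDR"), each = 20),
                        fd_RNFL = rnorm(40), `fd_GCL+IPL` = rnorm(40),
                        thickness_OPL = rnorm(40, 40, 3),
                        check.names = FALSE)
    sum(compare_layers(study)$significant, na.rm = TRUE)
  })
  expect_gte(mean(n_sig == 0), 0.95)
})
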