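test_that("Wald ratios follow the delta method", {
  h <- hframe(gamma = 0.1, se_gamma = 0.02, Gamma = 0.2, se_Gamma = 0.05)
  r <- waldRatio(h)
  expect_equal(r$ratio, 2)
  expect_equal(r$se_ratio, 0.5)
  expect_equal(r$weight, 4)

  # zero numerator: ratio 0, se = se_Gamma / |gamma|
  r0 <- waldRatio(hframe(0.1, 0.02, 0, 0.05))
  expect_equal(r0$ratio, 0)
  expect_equal(r0$se_ratio, 0.5)

  # second order adds the exposure-noise term
  r2 <- waldRatio(h, seOrder = "second")
  expect_equal(r2$se_ratio,
               sqrt(0.05^2 / 0.1^2 + 0.2^2 * 0.02^2 / 0.1^4))

  expect_error(waldRatio(hframe(0, 0.02, 0.1, 0.05)), "degenerate")
})

test_that("IVW matches closed forms and degenerate homogeneity", {
  # identical ratios: beta is that ratio, Q = 0, random-effects se = fixed se
  h <- hframe(gamma = c(0.1, 0.2, 0.4), se_gamma = 0.01,
              Gamma = 1.5 * c(0.1, 0.2, 0.4), se_Gamma = 0.01)
  est_r <- mrIVW(h, model = "random")
  est_f <- mrIVW(h, model = "fixed")
  expect_equal(mrBeta(est_r), 1.5)
  expect_equal(est_r@details$Q, 0)
  expect_equal(mrSE(est_r), mrSE(est_f))

  # J = 2, ratios {1, 3}, equal ratio ses of 1: beta = 2, fixed se = 1/sqrt(2)
  h2 <- hframe(gamma = c(1, 1), se_gamma = 0.01, Gamma = c(1, 3),
               se_Gamma = c(1, 1))
  e2 <- mrIVW(h2, model = "fixed")
  expect_equal(mrBeta(e2), 2)
  expect_equal(mrSE(e2), 1 / sqrt(2))

  expect_error(mrIVW(hframe(0.1, 0.01, 0.1, 0.01)), "insufficient")
})

test_that("IVW equals origin-constrained WLS and the DL option pools sanely", {
  set.seed(101)
  for (i in 1:25) {
    h <- rand_hframe(sample(3:40, 1))
    est <- mrIVW(h, model = "random")
    fit <- lm(Gamma ~ 0 + gamma, data = h, weights = 1 / h$se_Gamma^2)
    expect_equal(mrBeta(est), unname(coef(fit)), tolerance = 1e-10)
    # the lm slope se is the fixed IVW se scaled by sigma-hat; ours floors
    # the scaling at 1
    sg <- summary(fit)$sigma
    se_lm <- summary(fit)$coefficients[1, 2]
    expect_equal(mrSE(est), se_lm * max(1, sg) / sg, tolerance = 1e-10)
  }
  h <- rand_hframe(20)
  dl <- mrIVW(h, model = "dl")
  expect_true(is.finite(mrBeta(dl)) && mrSE(dl) >= mrSE(mrIVW(h, "fixed")))
})

test_that("MR-Egger recovers exact linear structure and is orientation-invariant", {
  g <- c(0.05, 0.08, 0.11, 0.14, 0.2)
  h <- hframe(gamma = g, se_gamma = 0.01, Gamma = 0.1 + 0.5 * g,
              se_Gamma = 0.02)
  e <- mrEgger(h)
  expect_equal(mrBeta(e), 0.5, tolerance = 1e-12)
  expect_equal(e@intercept, 0.1, tolerance = 1e-12)
  expect_equal(e@details$rss, 0, tolerance = 1e-20)

  # negating a record's gamma and Gamma on input changes nothing
  h2 <- h
  h2$gamma[2] <- -h2$gamma[2]
  h2$Gamma[2] <- -h2$Gamma[2]
  e2 <- mrEgger(h2)
  expect_equal(mrBeta(e2), mrBeta(e), tolerance = 1e-12)
  expect_equal(e2@intercept, e@intercept, tolerance = 1e-12)

  expect_error(mrEgger(hframe(c(1, 2), 0.1, c(1, 2), 0.1)), "insufficient")
  expect_error(mrEgger(hframe(c(1, 1, 1), 0.1, c(1, 2, 3), 0.1)),
               "collinearity")
})

test_that("MR-Egger agrees with a weighted lm oracle", {
  set.seed(202)
  for (i in 1:10) {
    h <- rand_hframe(sample(5:40, 1))
    e <- mrEgger(h)
    w <- 1 / h$se_Gamma^2
    fit <- lm(Gamma ~ gamma, data = h, weights = w) # gammas all positive
    expect_equal(mrBeta(e), unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(e@intercept, unname(coef(fit)[1]), tolerance = 1e-10)
    sg <- summary(fit)$sigma
    expect_equal(mrSE(e),
                 summary(fit)$coefficients[2, 2] * max(1, sg) / sg,
                 tolerance = 1e-10)
    # constraining the Egger intercept to zero is exactly IVW
    fit0 <- lm(Gamma ~ 0 + gamma, data = h, weights = w)
    expect_equal(mrBeta(mrIVW(h)), unname(coef(fit0)), tolerance = 1e-10)
  }
})

test_that("weighted median interpolates cumulative weight midpoints", {
  # equal weights, ratios {1,2,3}: the symmetric median
  h <- hframe(gamma = c(1, 1, 1), se_gamma = 0.01, Gamma = c(1, 2, 3),
              se_Gamma = c(1, 1, 1))
  expect_equal(mrBeta(mrWeightedMedian(h, nBoot = 0)), 2)

  # brute-force oracle on small random instances
  set.seed(303)
  for (i in 1:40) {
    h <- rand_hframe(sample(3:9, 1))
    r <- waldRatio(h)
    expect_equal(mrBeta(mrWeightedMedian(h, nBoot = 0)),
                 bf_weighted_median(r$ratio, r$weight), tolerance = 1e-12)
  }

  # all-equal ratios: the bootstrap se vanishes as the ratio ses do
  h_tight <- hframe(gamma = c(0.1, 0.2, 0.3), se_gamma = 1e-9,
                    Gamma = 0.7 * c(0.1, 0.2, 0.3), se_Gamma = 1e-9)
  est <- mrWeightedMedian(h_tight, nBoot = 200, seed = 4)
  expect_equal(mrBeta(est), 0.7, tolerance = 1e-9)
  expect_lt(mrSE(est), 1e-7)

  # seeded bootstrap is reproducible
  h <- rand_hframe(12)
  expect_identical(mrSE(mrWeightedMedian(h, nBoot = 300, seed = 9)),
                   mrSE(mrWeightedMedian(h, nBoot = 300, seed = 9)))
  expect_warning(mrWeightedMedian(h, nBoot = 50, seed = 1), "unstable")
  expect_error(mrWeightedMedian(h[1:2, ], nBoot = 0), "insufficient")
})

test_that("multivariable IVW fits jointly and reduces to univariable", {
  g1 <- c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3)
  g2 <- c(0.2, 0.05, 0.25, 0.1, 0.3, 0.15)
  d <- data.frame(gamma_x1 = g1, gamma_x2 = g2,
                  Gamma = 0.4 * g1 + 0.2 * g2, se_Gamma = 0.02)
  fits <- mrMultivariable(d)
  expect_named(fits, c("x1", "x2"))
  expect_equal(mrBeta(fits$x1), 0.4, tolerance = 1e-12)
  expect_equal(mrBeta(fits$x2), 0.2, tolerance = 1e-12)

  # single exposure column: identical to the IVW pooled estimate
  set.seed(404)
  h <- rand_hframe(15)
  d1 <- data.frame(gamma_x = h$gamma, Gamma = h$Gamma,
                   se_Gamma = h$se_Gamma)
  expect_equal(mrBeta(mrMultivariable(d1)$x), mrBeta(mrIVW(h)),
               tolerance = 1e-12)

  dc <- data.frame(gamma_a = g1, gamma_b = 2 * g1,
                   Gamma = 0.4 * g1, se_Gamma = 0.02)
  expect_error(mrMultivariable(dc), "rank deficiency")
  expect_error(mrMultivariable(d[1:2, ]), "insufficient")
})

test_that("odds-ratio reporting exponentiates estimate and CI", {
  est <- mrkit:::.mkEstimate("IVW", beta = 0, se = 0.1, pvalue = 1,
                             ciLow = -qnorm(0.975) * 0.1,
                             ciHigh = qnorm(0.975) * 0.1, nsnp = 10)
  or <- mrOR(toOddsRatio(est))
  expect_equal(unname(or["or"]), 1)
  expect_equal(unname(or["low"]), 0.822, tolerance = 1e-3)
  expect_equal(unname(or["high"]), 1.217, tolerance = 1e-3)

  est2 <- mrkit:::.mkEstimate("IVW", beta = log(2), se = 0.1, pvalue = 0.1,
                              ciLow = log(2) - 0.196,
                              ciHigh = log(2) + 0.196, nsnp = 10)
  expect_equal(unname(mrOR(toOddsRatio(est2))["or"]), 2)

  # monotonicity in beta at fixed se
  betas <- seq(-1, 1, by = 0.25)
  ors <- vapply(betas, function(b) {
    e <- mrkit:::.mkEstimate("IVW", b, 0.1, 0.5, b - 0.196, b + 0.196, 5L)
    unname(mrOR(toOddsRatio(e))["or"])
  }, numeric(1))
  expect_true(all(diff(ors) > 0))
})
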