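test_that("the generator is deterministic and internally consistent", {
  cfg <- simConfig(J = 200)
  s1 <- simulateSummaryStats(cfg, simTruth(theta = 0.2, seed = 123))
  s2 <- simulateSummaryStats(cfg, simTruth(theta = 0.2, seed = 123))
  expect_identical(variantData(s1$exposure), variantData(s2$exposure))
  expect_identical(variantData(s1$outcome), variantData(s2$outcome))
  expect_identical(s1$truth$gammaTrue, s2$truth$gammaTrue)

  # p-values are exact functions of the z-scores (floored at a representable
  # positive value)
  d <- variantData(s1$exposure)
  expect_equal(d$pvalue, pmax(2 * pnorm(-abs(d$beta / d$se)), 1e-300),
               tolerance = 1e-15)
  do <- variantData(s1$outcome)
  expect_equal(do$pvalue, pmax(2 * pnorm(-abs(do$beta / do$se)), 1e-300),
               tolerance = 1e-15)

  # two-sample design: exposure and outcome noise are independent draws
  noise_e <- d$beta - s1$truth$gammaTrue
  noise_o <- do$beta - 0.2 * s1$truth$gammaTrue
  expect_lt(abs(cor(noise_e, noise_o)), 0.2)

  # instruments are genome-wide significant by construction
  expect_true(all(d$pvalue < 5e-8))
})

test_that("observed exposure effects are unbiased for the truth", {
  sim <- simulateSummaryStats(simConfig(J = 10000),
                              simTruth(theta = 0, seed = 77))
  err <- variantData(sim$exposure)$beta - sim$truth$gammaTrue
  # Monte-Carlo error of the mean at J = 1e4: se = 0.003/100
  expect_lt(abs(mean(err)), 4 * 0.003 / sqrt(10000))
})

test_that("pleiotropy modes shape the direct effects as declared", {
  cfg <- simConfig(J = 2000)
  bal <- simulateSummaryStats(cfg, simTruth(
    theta = 0, pleiotropyMode = "balanced", sigmaAlpha = 0.02, seed = 5))
  expect_equal(mean(bal$truth$alpha), 0, tolerance = 0.002)
  expect_length(bal$truth$invalidIds, 2000)

  dir <- simulateSummaryStats(cfg, simTruth(
    theta = 0, pleiotropyMode = "directional", muAlpha = 0.05,
    sigmaAlpha = 0.02, propInvalid = 0.5, seed = 6))
  inv <- dir$truth$variant_id %in% dir$truth$invalidIds
  expect_length(dir$truth$invalidIds, 1000)
  expect_lt(abs(mean(dir$truth$alpha[inv]) - 0.05), 0.005)
  expect_true(all(dir$truth$alpha[!inv] == 0))

  ins <- simulateSummaryStats(cfg, simTruth(
    theta = 0, pleiotropyMode = "inside_violating", muAlpha = 0.05,
    sigmaAlpha = 0.02, seed = 7))
  expect_gt(cor(ins$truth$alpha, ins$truth$gammaTrue), 0.5)

  # outcome effects follow Gamma = theta*gamma + alpha exactly (pre-noise)
  sim <- simulateSummaryStats(simConfig(J = 500, seOutcome = 1e-9),
                              simTruth(theta = 0.4,
                                       pleiotropyMode = "directional",
                                       muAlpha = 0.03, seed = 8))
  expect_equal(variantData(sim$outcome)$beta,
               0.4 * sim$truth$gammaTrue + sim$truth$alpha,
               tolerance = 1e-6)
})

test_that("outlier injection is local, signed and seeded", {
  sim <- simulateSummaryStats(simConfig(J = 50),
                              simTruth(theta = 0.1, seed = 9))
  ids <- variantData(sim$outcome)$variant_id[c(3, 10, 20)]

  expect_identical(variantData(injectOutliers(sim$outcome, character(0), 10)),
                   variantData(sim$outcome))
  expect_equal(variantData(injectOutliers(sim$outcome, ids, 0))$beta,
               variantData(sim$outcome)$beta)

  shifted <- injectOutliers(sim$outcome, ids, 10, seed = 2)
  delta <- variantData(shifted)$beta - variantData(sim$outcome)$beta
  hit <- variantData(sim$outcome)$variant_id %in% ids
  expect_true(all(delta[!hit] == 0))
  expect_equal(abs(delta[hit]) / variantData(sim$outcome)$se[hit],
               rep(10, 3))
  expect_identical(variantData(injectOutliers(sim$outcome, ids, 10, seed = 2)),
                   variantData(shifted))
  up <- injectOutliers(sim$outcome, ids, 10, direction = "up")
  expect_true(all((variantData(up)$beta - variantData(sim$outcome)$beta)[hit]
                  > 0))
  expect_error(injectOutliers(sim$outcome, "rs_nope", 10), "unknown")
})

test_that("LD blocks collapse to one index variant per block under clumping", {
  cfg <- simConfig(J = 30, ldBlocks = list(size = 5, r2 = 0.9))
  sim <- simulateSummaryStats(cfg, simTruth(theta = 0.2, seed = 10))
  expect_s3_class(sim$ld, "data.frame")
  expect_equal(nrow(sim$ld), 6 * choose(5, 2))
  kept <- ldClump(variantData(sim$exposure)$variant_id, sim$exposure,
                  sim$ld, r2Threshold = 0.5, windowKb = 10000)
  expect_length(kept, 6)
  # at the stringent default threshold (0.001) the same blocks collapse
  kept2 <- ldClump(variantData(sim$exposure)$variant_id, sim$exposure,
                   sim$ld)
  expect_length(kept2, 6)
})

test_that("covariate mediation behaves as declared at its limits", {
  cfg <- simConfig(J = 80)
  sim <- simulateMediation(cfg, thetaDirect = 0.2, mediatorEffect = 0.3,
                           seed = 33)
  expect_identical(
    variantData(sim$exposure),
    variantData(simulateMediation(cfg, thetaDirect = 0.2,
                                  mediatorEffect = 0.3, seed = 33)$exposure))
  med <- sim$truth$variant_id %in% sim$truth$mediatedIds
  expect_equal(sum(med), 40)
  expect_true(all(sim$truth$delta[!med] == 0))

  # no mediation: univariable and multivariable agree within MC error
  reps <- t(vapply(1:30, function(i) {
    s <- simulateMediation(cfg, thetaDirect = 0.2, mediatorEffect = 0,
                           seed = 1000 + i)
    hp <- harmonizePair(s$exposure, s$outcome)
    mh <- harmonizeMulti(list(s$exposure, s$covariate), s$outcome)
    c(uni = mrBeta(mrIVW(hp)),
      mv = mrBeta(mrMultivariable(mh)[["exposure"]]))
  }, numeric(2)))
  expect_lt(abs(mean(reps[, "uni"]) - mean(reps[, "mv"])), 0.01)
  expect_lt(abs(mean(reps[, "uni"]) - 0.2), 0.02)
})
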