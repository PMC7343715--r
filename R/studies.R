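# Replicated simulation studies: calibration, recovery, MR-PRESSO operating
# characteristics, and covariate-mediated pleiotropy. These drive the
# package's own validation and are exported so the same study definitions
# can be rerun from scripts.

.rep_seeds <- function(seed, n) {
  .withSeed(seed, function() sample.int(2^31 - 2, n))
}

# Simulate one replicate and return the harmonized exposure-outcome pair.
.sim_pair <- function(config, truth) {
  sim <- simulateSummaryStats(config, truth)
  harmonizePair(sim$exposure, sim$outcome)
}

#' Null calibration of IVW, the Egger intercept test and Cochran's Q
#'
#' Simulates replicate two-sample datasets under the sharp null (no causal
#' effect, no pleiotropy) and reports the empirical type-I error of the IVW
#' causal test and of the MR-Egger intercept test at `alpha`, together with
#' the Cochran's Q p-values (uniform under the homogeneous null) and their
#' Kolmogorov-Smirnov uniformity p-value.
#'
#' @param nRep replicates (default 1000).
#' @param J instruments per replicate (default 100).
#' @param alpha test level (default 0.05).
#' @param seed study seed.
#' @param config optional [SimConfig-class] overriding the default structure
#'   (J is taken from the `J` argument).
#' @return list with `ivwType1`, `eggerInterceptType1`, `qPvalues`, `ksP`,
#'   `nRep`, `J`.
#' @export
calibrationStudy <- function(nRep = 1000, J = 100, alpha = 0.05, seed = 1,
                             config = NULL) {
  config <- config %||% simConfig(J = J)
  seeds <- .rep_seeds(seed, nRep)
  ivw_p <- egger_p <- q_p <- numeric(nRep)
  for (i in seq_len(nRep)) {
    hp <- .sim_pair(config, simTruth(theta = 0, pleiotropyMode = "none",
                                     seed = seeds[i]))
    ivw_p[i] <- mrPvalue(mrIVW(hp))
    egger_p[i] <- mrIntercept(mrEgger(hp))[["p"]]
    q_p[i] <- cochranQ(hp)@pvalue
  }
  list(ivwType1 = mean(ivw_p < alpha),
       eggerInterceptType1 = mean(egger_p < alpha),
       qPvalues = q_p,
       ksP = stats::ks.test(q_p, "punif")$p.value,
       nRep = nRep, J = J)
}

#' Recovery of a known causal effect under different pleiotropy regimes
#'
#' Scenarios (all with true effect `theta`):
#' \describe{
#'   \item{`"none"`}{no pleiotropy; reports the mean IVW estimate.}
#'   \item{`"directional"`}{all instruments carry directional pleiotropy
#'     (mean `muAlpha = 0.05`, sd 0.02) with InSIDE holding; reports the mean
#'     MR-Egger slope (consistent) and the mean IVW estimate (biased by
#'     roughly `muAlpha / mean(gamma)`).}
#'   \item{`"invalid30"`}{30% of instruments carry large one-sided
#'     pleiotropic offsets (mean 0.1); reports the mean weighted-median
#'     estimate (consistent under majority validity) and the mean IVW.}
#' }
#' The scenario outcome se (default 0.003) reflects a large continuous-
#' outcome GWAS.
#'
#' @param scenario one of `"none"`, `"directional"`, `"invalid30"`.
#' @param nRep replicates (default 500).
#' @param J instruments per replicate (default 150).
#' @param theta true causal effect (default 0.3).
#' @param seed study seed.
#' @param seOutcome outcome-side sampling se (default 0.003).
#' @return list with scenario-appropriate mean estimates, `theta`, `nRep`.
#' @export
recoveryStudy <- function(scenario = c("none", "directional", "invalid30"),
                          nRep = 500, J = 150, theta = 0.3, seed = 1,
                          seOutcome = 0.003) {
  scenario <- match.arg(scenario)
  config <- simConfig(J = J, seOutcome = seOutcome)
  seeds <- .rep_seeds(seed, nRep)
  truth_for <- function(s) switch(scenario,
    none = simTruth(theta = theta, pleiotropyMode = "none", seed = s),
    directional = simTruth(theta = theta, pleiotropyMode = "directional",
                           muAlpha = 0.05, sigmaAlpha = 0.02,
                           propInvalid = 1, seed = s),
    invalid30 = simTruth(theta = theta, pleiotropyMode = "directional",
                         muAlpha = 0.1, sigmaAlpha = 0.02,
                         propInvalid = 0.3, seed = s))
  ivw <- egger <- wmed <- numeric(nRep)
  for (i in seq_len(nRep)) {
    hp <- .sim_pair(config, truth_for(seeds[i]))
    ivw[i] <- mrBeta(mrIVW(hp))
    if (scenario == "directional") egger[i] <- mrBeta(mrEgger(hp))
    if (scenario == "invalid30")
      wmed[i] <- mrBeta(mrWeightedMedian(hp, nBoot = 0))
  }
  out <- list(scenario = scenario, theta = theta, nRep = nRep, J = J,
              ivwMean = mean(ivw))
  if (scenario == "directional") out$eggerMean <- mean(egger)
  if (scenario == "invalid30") out$weightedMedianMean <- mean(wmed)
  out
}

#' MR-PRESSO operating characteristics under injected outliers
#'
#' Each replicate simulates a clean dataset (true effect `theta`), shifts a
#' `propOutlier` fraction of outcome effects by `shiftSeUnits` standard
#' errors in the same direction (a shared pleiotropic pathway), and runs the
#' full MR-PRESSO procedure. Reported: power of the global test at 0.05,
#' pooled outlier recall and precision of the Bonferroni-adjusted outlier
#' test, and the fraction of replicates where the corrected estimate is
#' strictly closer to the truth than the uncorrected one.
#'
#' `nSim` defaults to 5000 here: the Bonferroni-adjusted empirical p cannot
#' fall below `J / (nSim + 1)`, so the module default of 1000 would give the
#' outlier test no resolution at J = 100.
#'
#' @param nRep replicates (default 200).
#' @param J instruments per replicate (default 100).
#' @param propOutlier fraction of instruments shifted (default 0.1).
#' @param shiftSeUnits shift in se units (default 10).
#' @param theta true causal effect (default 0.3).
#' @param nSim PRESSO simulations per replicate (default 5000).
#' @param seed study seed.
#' @return list with `globalPower`, `recall`, `precision`,
#'   `correctionImprovement`, `nRep`.
#' @export
pressoStudy <- function(nRep = 200, J = 100, propOutlier = 0.1,
                        shiftSeUnits = 10, theta = 0.3, nSim = 5000,
                        seed = 1) {
  config <- simConfig(J = J)
  seeds <- .rep_seeds(seed, nRep)
  m <- round(propOutlier * J)
  global_sig <- improved <- logical(nRep)
  tp <- fp <- fn <- 0L
  for (i in seq_len(nRep)) {
    res <- .withSeed(seeds[i], function() {
      sim <- simulateSummaryStats(
        config, simTruth(theta = theta, pleiotropyMode = "none",
                         seed = seeds[i]))
      true_out <- sample(sim$truth$variant_id, m)
      outcome <- injectOutliers(sim$outcome, true_out, shiftSeUnits,
                                direction = "up")
      hp <- harmonizePair(sim$exposure, outcome)
      fit <- mrPresso(hp, nSim = nSim)
      list(fit = fit, true_out = true_out)
    })
    fit <- res$fit
    flagged <- fit@outlierIds
    tp <- tp + length(intersect(flagged, res$true_out))
    fp <- fp + length(setdiff(flagged, res$true_out))
    fn <- fn + length(setdiff(res$true_out, flagged))
    global_sig[i] <- fit@globalP < 0.05
    improved[i] <- abs(fit@corrected@beta - theta) <
                   abs(fit@uncorrected@beta - theta)
  }
  list(globalPower = mean(global_sig),
       recall = tp / (tp + fn),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       correctionImprovement = mean(improved),
       nRep = nRep, J = J)
}

#' Univariable vs multivariable MR under covariate-mediated pleiotropy
#'
#' Each replicate simulates a null direct effect (`thetaDirect = 0`) with a
#' covariate mediating part of the instruments' outcome effects
#' ([simulateMediation()]); the univariable IVW rejection rate at `alpha`
#' measures the pleiotropy-induced false-positive rate, while multivariable
#' IVW adjusting for the covariate should stay near the nominal level.
#'
#' @param nRep replicates (default 200).
#' @param J instruments per replicate (default 100).
#' @param mediatorEffect covariate effect on the outcome (default 0.3).
#' @param alpha test level (default 0.05).
#' @param seed study seed.
#' @return list with `univariableRejection`, `multivariableType1`, `nRep`.
#' @export
mediationStudy <- function(nRep = 200, J = 100, mediatorEffect = 0.3,
                           alpha = 0.05, seed = 1) {
  config <- simConfig(J = J)
  seeds <- .rep_seeds(seed, nRep)
  uni_p <- mv_p <- numeric(nRep)
  for (i in seq_len(nRep)) {
    sim <- simulateMediation(config, thetaDirect = 0,
                             mediatorEffect = mediatorEffect,
                             seed = seeds[i])
    hp <- harmonizePair(sim$exposure, sim$outcome)
    uni_p[i] <- mrPvalue(mrIVW(hp))
    mh <- harmonizeMulti(list(sim$exposure, sim$covariate), sim$outcome)
    mv_p[i] <- mrPvalue(mrMultivariable(mh)[["exposure"]])
  }
  list(univariableRejection = mean(uni_p < alpha),
       multivariableType1 = mean(mv_p < alpha),
       nRep = nRep, J = J)
}
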