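#' Simulation configuration
#'
#' Defaults emulate the structure of large consortium GWAS: per-allele true
#' exposure effects drawn uniformly from 0.02-0.10 SD with an exposure-side
#' standard error of 0.003 (instrument F roughly 40-1000, all genome-wide
#' significant by construction) and an outcome-side standard error of 0.02.
#'
#' @param J number of instruments (>= 3).
#' @param seExposure,seOutcome sampling standard errors of the per-allele
#'   effect estimates in the two (independent) samples.
#' @param effectRange range of true exposure-effect magnitudes (trait SD per
#'   allele; instruments are oriented to the trait-increasing allele).
#' @param eafRange range of simulated effect-allele frequencies.
#' @param outcomeScale `"continuous"` (unit `"SD"`) or `"log_odds"` (binary
#'   outcome; effects generated directly on the log-odds scale).
#' @param ldBlocks optional `list(size =, r2 =)`: variants are laid out in
#'   consecutive same-chromosome blocks of `size` with pairwise within-block
#'   squared correlation `r2`, and the pairwise table is returned for
#'   clumping tests.
#' @param propPalindromic fraction of variants assigned palindromic (A/T or
#'   C/G) alleles (default 0).
#' @param nSampleExposure,nSampleOutcome nominal sample sizes recorded in
#'   the `n` column.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(J = 100, seExposure = 0.003, seOutcome = 0.02,
                      effectRange = c(0.02, 0.10), eafRange = c(0.05, 0.95),
                      outcomeScale = c("continuous", "log_odds"),
                      ldBlocks = NULL, propPalindromic = 0,
                      nSampleExposure = 7e5, nSampleOutcome = 2e5) {
  outcomeScale <- match.arg(outcomeScale)
  new("SimConfig", J = as.integer(J), seExposure = seExposure,
      seOutcome = seOutcome, effectRange = effectRange, eafRange = eafRange,
      outcomeScale = outcomeScale, ldBlocks = ldBlocks %||% list(),
      propPalindromic = propPalindromic,
      nSampleExposure = nSampleExposure, nSampleOutcome = nSampleOutcome)
}

#' Simulation ground truth
#'
#' @param theta true causal effect of the exposure on the outcome (outcome
#'   units per exposure SD).
#' @param pleiotropyMode `"none"`, `"balanced"` (mean-zero direct effects),
#'   `"directional"` (mean `muAlpha`), or `"inside_violating"` (direct
#'   effects correlated with instrument strength, violating InSIDE).
#' @param muAlpha,sigmaAlpha mean and sd of the pleiotropic direct effects.
#' @param propInvalid fraction of instruments receiving a pleiotropic effect
#'   (default 1 when a pleiotropy mode is active, ignored for `"none"`).
#' @param seed RNG seed (required).
#' @return a [SimTruth-class].
#' @export
simTruth <- function(theta = 0,
                     pleiotropyMode = c("none", "balanced", "directional",
                                        "inside_violating"),
                     muAlpha = 0, sigmaAlpha = 0.02, propInvalid = 1,
                     seed) {
  pleiotropyMode <- match.arg(pleiotropyMode)
  if (missing(seed)) stop("seed is required")
  new("SimTruth", theta = theta, pleiotropyMode = pleiotropyMode,
      muAlpha = muAlpha, sigmaAlpha = sigmaAlpha,
      propInvalid = propInvalid, seed = seed)
}

.NONPAL_PAIRS <- matrix(c("A","C", "A","G", "C","A", "C","T",
                          "G","A", "G","T", "T","C", "T","G"),
                        ncol = 2, byrow = TRUE)
.PAL_PAIRS <- matrix(c("A","T", "T","A", "C","G", "G","C"),
                     ncol = 2, byrow = TRUE)

# Variant skeleton shared by the generators: ids, coordinates, alleles, eaf.
.sim_variants <- function(config) {
  J <- config@J
  ids <- sprintf("rs%07d", seq_len(J))
  if (length(config@ldBlocks)) {
    size <- config@ldBlocks$size
    nblock <- ceiling(J / size)
    block <- rep(seq_len(nblock), each = size)[seq_len(J)]
    chrom <- as.character(((block - 1) %% 22) + 1)
    pos <- block * 5e6 + (seq_len(J) - (block - 1) * size) * 10000
  } else {
    block <- NULL
    chrom <- as.character(sample.int(22, J, replace = TRUE))
    pos <- sample.int(2.5e8, J, replace = TRUE)
  }
  pal <- stats::runif(J) < config@propPalindromic
  pick_np <- sample.int(nrow(.NONPAL_PAIRS), J, replace = TRUE)
  pick_p <- sample.int(nrow(.PAL_PAIRS), J, replace = TRUE)
  ea <- ifelse(pal, .PAL_PAIRS[pick_p, 1], .NONPAL_PAIRS[pick_np, 1])
  oa <- ifelse(pal, .PAL_PAIRS[pick_p, 2], .NONPAL_PAIRS[pick_np, 2])
  eaf <- stats::runif(J, config@eafRange[1], config@eafRange[2])
  list(ids = ids, chrom = chrom, pos = pos, ea = ea, oa = oa, eaf = eaf,
       block = block)
}

.sim_dataset <- function(trait, unit, v, beta_true, se, n) {
  J <- length(beta_true)
  beta <- beta_true + stats::rnorm(J, 0, se)
  data <- data.frame(variant_id = v$ids, chrom = v$chrom, pos = v$pos,
                     effect_allele = v$ea, other_allele = v$oa, eaf = v$eaf,
                     beta = beta, se = rep(se, J),
                     pvalue = .z2p(beta / se), n = rep(n, J),
                     stringsAsFactors = FALSE)
  gwasSummary(trait = trait, unit = unit, data = data)
}

.ld_table <- function(v, r2) {
  if (is.null(v$block)) return(NULL)
  rows <- lapply(split(seq_along(v$block), v$block), function(idx) {
    if (length(idx) < 2) return(NULL)
    cmb <- utils::combn(idx, 2)
    data.frame(id_a = v$ids[cmb[1, ]], id_b = v$ids[cmb[2, ]], r2 = r2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Generative model, on the summary-statistic scale:
#' true exposure effects `gamma_j` drawn from `effectRange` (oriented to the
#' trait-increasing allele); pleiotropic direct effects `alpha_j` per the
#' truth's pleiotropy mode (zero; mean-zero; mean `muAlpha`; or correlated
#' with `gamma_j` for the InSIDE-violating mode), applied to a random
#' `propInvalid` fraction of instruments; true outcome effects
#' `Gamma_j = theta * gamma_j + alpha_j`. Observed effects add independent
#' normal noise at the configured standard errors in each sample (the
#' two-sample design) and p-values are exact: `p = 2 * pnorm(-|beta/se|)`.
#'
#' @param config a [SimConfig-class].
#' @param truth a [SimTruth-class] (carries the seed).
#' @return list with elements `exposure` and `outcome` ([GwasSummary-class]),
#'   `ld` (pairwise r2 data.frame, or `NULL` without LD blocks) and `truth`
#'   (a list with the generating parameters and the realized `gammaTrue`,
#'   `alpha` and `invalidIds`), suitable for serialization as a sidecar.
#' @export
simulateSummaryStats <- function(config, truth) {
  stopifnot(is(config, "SimConfig"), is(truth, "SimTruth"))
  .withSeed(truth@seed, function() {
    J <- config@J
    v <- .sim_variants(config)
    gammaTrue <- stats::runif(J, config@effectRange[1], config@effectRange[2])

    alpha <- numeric(J)
    invalid <- rep(FALSE, J)
    if (truth@pleiotropyMode != "none" && truth@propInvalid > 0) {
      invalid <- seq_len(J) %in%
        sample.int(J, round(truth@propInvalid * J))
      nI <- sum(invalid)
      a <- switch(truth@pleiotropyMode,
        balanced = stats::rnorm(nI, 0, truth@sigmaAlpha),
        directional = stats::rnorm(nI, truth@muAlpha, truth@sigmaAlpha),
        inside_violating = {
          # direct effects correlated (~0.8) with instrument strength
          z <- as.numeric(scale(gammaTrue[invalid]))
          truth@muAlpha + truth@sigmaAlpha *
            (0.8 * z + sqrt(1 - 0.8^2) * stats::rnorm(nI))
        })
      alpha[invalid] <- a
    }
    GammaTrue <- truth@theta * gammaTrue + alpha

    outUnit <- if (config@outcomeScale == "log_odds") "log odds" else "SD"
    exposure <- .sim_dataset("exposure", "SD", v, gammaTrue,
                             config@seExposure, config@nSampleExposure)
    outcome <- .sim_dataset("outcome", outUnit, v, GammaTrue,
                            config@seOutcome, config@nSampleOutcome)
    if (!any(exposure@data$pvalue < 5e-8))
      stop("generation error: no genome-wide-significant instruments; ",
           "raise effectRange or lower seExposure")

    ld <- if (length(config@ldBlocks))
      .ld_table(v, config@ldBlocks$r2) else NULL
    list(exposure = exposure, outcome = outcome, ld = ld,
         truth = list(theta = truth@theta,
                      pleiotropyMode = truth@pleiotropyMode,
                      muAlpha = truth@muAlpha,
                      sigmaAlpha = truth@sigmaAlpha,
                      propInvalid = truth@propInvalid,
                      seed = truth@seed,
                      variant_id = v$ids, gammaTrue = gammaTrue,
                      alpha = alpha, invalidIds = v$ids[invalid]))
  })
}

#' Inject pleiotropic outliers into an outcome dataset
#'
#' Shifts the outcome effect of the selected variants by
#' `shiftSeUnits * se`; all other records are untouched. P-values are
#' recomputed so the dataset stays internally consistent. `direction`
#' `"random"` draws an independent sign per variant (seeded); `"up"`/`"down"`
#' shift all selected variants the same way (a shared pleiotropic pathway).
#'
#' @param outcome a [GwasSummary-class].
#' @param ids variants to shift (must exist in the dataset).
#' @param shiftSeUnits shift magnitude in units of each variant's se.
#' @param seed seed for the random signs (`NULL` = current stream).
#' @param direction `"random"` (default), `"up"`, or `"down"`.
#' @return the modified [GwasSummary-class].
#' @export
injectOutliers <- function(outcome, ids, shiftSeUnits, seed = NULL,
                           direction = c("random", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(is(outcome, "GwasSummary"))
  ids <- as.character(ids)
  idx <- match(ids, outcome@data$variant_id)
  if (anyNA(idx))
    stop("unknown variant id(s): ",
         paste(head(ids[is.na(idx)], 5), collapse = ", "))
  if (!length(idx)) return(outcome)
  signs <- switch(direction,
    random = .withSeed(seed, function()
      sample(c(-1, 1), length(idx), replace = TRUE)),
    up = rep(1, length(idx)),
    down = rep(-1, length(idx)))
  d <- outcome@data
  d$beta[idx] <- d$beta[idx] + signs * shiftSeUnits * d$se[idx]
  d$pvalue[idx] <- .z2p(d$beta[idx] / d$se[idx])
  outcome@data <- d
  outcome
}

#' Simulate covariate-mediated pleiotropy
#'
#' A fraction of the exposure's instruments also affects a heritable
#' covariate (effect `delta_j = thetaMediator * gamma_j + noise`, so the
#' covariate effects are correlated with instrument strength, as for
#' genetically correlated traits), and the covariate affects the outcome.
#' True outcome effects are
#' `Gamma_j = thetaDirect * gamma_j + mediatorEffect * delta_j`: univariable
#' MR of exposure on outcome is confounded by the mediated path, while
#' multivariable MR adjusting for the covariate targets `thetaDirect`.
#'
#' @param config a [SimConfig-class] (`seExposure`/`seOutcome` as usual).
#' @param thetaDirect true direct effect of the exposure on the outcome.
#' @param thetaMediator per-unit effect of instrument strength on the
#'   covariate for mediated instruments (default 0.5).
#' @param mediatorEffect effect of the covariate on the outcome.
#' @param propMediated fraction of instruments affecting the covariate
#'   (default 0.5).
#' @param mediatorNoise sd of the instrument-specific covariate-effect noise
#'   (default 0.02).
#' @param seMediator sampling se of the covariate GWAS (default 0.005).
#' @param seed RNG seed (required).
#' @return list with `exposure`, `covariate`, `outcome`
#'   ([GwasSummary-class]) and a `truth` list.
#' @export
simulateMediation <- function(config, thetaDirect, thetaMediator = 0.5,
                              mediatorEffect = 0.3, propMediated = 0.5,
                              mediatorNoise = 0.02, seMediator = 0.005,
                              seed) {
  stopifnot(is(config, "SimConfig"))
  if (missing(seed)) stop("seed is required")
  .withSeed(seed, function() {
    J <- config@J
    v <- .sim_variants(config)
    gammaTrue <- stats::runif(J, config@effectRange[1], config@effectRange[2])
    mediated <- seq_len(J) %in% sample.int(J, round(propMediated * J))
    delta <- ifelse(mediated,
                    thetaMediator * gammaTrue +
                      stats::rnorm(J, 0, mediatorNoise),
                    0)
    GammaTrue <- thetaDirect * gammaTrue + mediatorEffect * delta

    outUnit <- if (config@outcomeScale == "log_odds") "log odds" else "SD"
    exposure <- .sim_dataset("exposure", "SD", v, gammaTrue,
                             config@seExposure, config@nSampleExposure)
    covariate <- .sim_dataset("covariate", "SD", v, delta, seMediator,
                              config@nSampleExposure)
    outcome <- .sim_dataset("outcome", outUnit, v, GammaTrue,
                            config@seOutcome, config@nSampleOutcome)
    if (!any(exposure@data$pvalue < 5e-8))
      stop("generation error: no genome-wide-significant instruments")
    list(exposure = exposure, covariate = covariate, outcome = outcome,
         truth = list(thetaDirect = thetaDirect,
                      thetaMediator = thetaMediator,
                      mediatorEffect = mediatorEffect,
                      propMediated = propMediated, seed = seed,
                      variant_id = v$ids, gammaTrue = gammaTrue,
                      delta = delta, mediatedIds = v$ids[mediated]))
  })
}
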