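# Central S4 containers. Validity is enforced at construction time so the
# estimators can assume clean inputs downstream.

.GWAS_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pvalue", "n")

.ALLELES <- c("A", "C", "G", "T")

.ACTIONS <- c("kept", "flipped", "dropped_palindromic",
              "dropped_incompatible", "dropped_missing")

#' GwasSummary: one trait's GWAS summary statistics
#'
#' One row per variant: identifier, genomic coordinates, effect/other allele,
#' effect-allele frequency, per-allele effect size with its standard error,
#' p-value and (optionally) sample size. The `unit` records the scale the
#' effect sizes are expressed on (e.g. `"SD"`, `"mmol/L"`, `"log odds"`).
#'
#' @slot trait trait name.
#' @slot unit unit of the per-allele effect.
#' @slot data data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#' @slot dropLog named list of row counts dropped during reading/validation.
#' @exportClass GwasSummary
setClass("GwasSummary",
  slots = c(trait = "character", unit = "character",
            data = "data.frame", dropLog = "list"))

setValidity("GwasSummary", function(object) {
  d <- object@data
  msg <- character()
  miss <- setdiff(.GWAS_COLS, names(d))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(d$variant_id))
    msg <- c(msg, "variant_id must be unique within a dataset")
  if (nrow(d)) {
    if (!all(d$effect_allele %in% .ALLELES) ||
        !all(d$other_allele %in% .ALLELES))
      msg <- c(msg, "alleles must be one of A/C/G/T")
    if (any(d$effect_allele == d$other_allele))
      msg <- c(msg, "effect_allele must differ from other_allele")
    if (any(!is.finite(d$se) | d$se <= 0))
      msg <- c(msg, "se must be finite and > 0")
    bad_eaf <- !is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1)
    if (any(bad_eaf)) msg <- c(msg, "eaf must lie in [0, 1] or be missing")
    if (any(!is.finite(d$pvalue) | d$pvalue <= 0 | d$pvalue > 1))
      msg <- c(msg, "pvalue must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' HarmonizedPair: exposure and outcome effects on a shared effect allele
#'
#' One row per requested variant. Rows with `action` `"kept"` or `"flipped"`
#' carry the exposure effect (`gamma`, `se_gamma`) and the outcome effect
#' (`Gamma`, `se_Gamma`) expressed on the same effect allele; dropped rows
#' keep their drop reason and `NA` effects so that per-stage counts always
#' reconcile with the number of requested variants.
#'
#' @slot exposure,outcome trait names.
#' @slot exposureUnit,outcomeUnit effect units.
#' @slot eafWindow the palindromic ambiguity window used.
#' @slot data data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `gamma`, `se_gamma`, `Gamma`, `se_Gamma`,
#'   `exposure_eaf`, `outcome_eaf`, `action`.
#' @exportClass HarmonizedPair
setClass("HarmonizedPair",
  slots = c(exposure = "character", outcome = "character",
            exposureUnit = "character", outcomeUnit = "character",
            eafWindow = "numeric", data = "data.frame"))

setValidity("HarmonizedPair", function(object) {
  d <- object@data
  need <- c("variant_id", "effect_allele", "other_allele", "gamma",
            "se_gamma", "Gamma", "se_Gamma", "exposure_eaf", "outcome_eaf",
            "action")
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (!all(d$action %in% .ACTIONS))
    return("unknown harmonization action")
  keep <- d$action %in% c("kept", "flipped")
  if (any(keep) && any(!is.finite(d$gamma[keep]) | !is.finite(d$Gamma[keep]) |
                       d$se_gamma[keep] <= 0 | d$se_Gamma[keep] <= 0))
    return("retained records must have finite effects and positive ses")
  TRUE
})

#' HarmonizedMulti: multivariable harmonized table
#'
#' Variants harmonizable across every exposure/covariate dataset and the
#' outcome, all effects expressed on one shared allele per variant. Columns:
#' `variant_id`, one `gamma_<name>` / `se_gamma_<name>` pair per exposure,
#' then `Gamma`, `se_Gamma`.
#'
#' @exportClass HarmonizedMulti
setClass("HarmonizedMulti",
  slots = c(exposures = "character", outcome = "character",
            outcomeUnit = "character", data = "data.frame"))

#' InstrumentSet: selected instruments with strength statistics
#'
#' @slot variantIds instrument ids, in selection order.
#' @slot fstat named per-variant F statistics, `F = (beta/se)^2`.
#' @slot weakThreshold F threshold below/at which instruments are flagged.
#' @slot weakIds flagged (not removed) weak instruments.
#' @slot selectionLog named counts at each filter stage.
#' @exportClass InstrumentSet
setClass("InstrumentSet",
  slots = c(variantIds = "character", fstat = "numeric",
            weakThreshold = "numeric", weakIds = "character",
            selectionLog = "list"))

setValidity("InstrumentSet", function(object) {
  if (anyDuplicated(object@variantIds)) return("instrument ids must be unique")
  if (length(object@fstat) != length(object@variantIds))
    return("one F statistic per instrument required")
  if (any(object@fstat < 0)) return("F statistics must be nonnegative")
  TRUE
})

#' MRestimate: a method-labelled causal-effect estimate
#'
#' Effect per SD (or unit) of exposure on the outcome scale, with 95% CI and
#' p-value; `or`/`orLow`/`orHigh` hold the exponentiated scale once
#' [toOddsRatio()] has been applied. Intercept slots are populated only for
#' MR-Egger.
#'
#' @exportClass MRestimate
setClass("MRestimate",
  slots = c(method = "character", exposure = "character", outcome = "character",
            outcomeUnit = "character",
            beta = "numeric", se = "numeric", ciLow = "numeric",
            ciHigh = "numeric", pvalue = "numeric", nsnp = "integer",
            or = "numeric", orLow = "numeric", orHigh = "numeric",
            intercept = "numeric", seIntercept = "numeric",
            interceptCiLow = "numeric", interceptCiHigh = "numeric",
            pIntercept = "numeric", details = "list"))

setValidity("MRestimate", function(object) {
  if (is.finite(object@beta) && is.finite(object@ciLow) &&
      is.finite(object@ciHigh) &&
      (object@ciLow > object@beta || object@beta > object@ciHigh))
    return("ciLow <= beta <= ciHigh violated")
  TRUE
})

#' HetTest: Cochran's Q heterogeneity test
#' @exportClass HetTest
setClass("HetTest",
  slots = c(Q = "numeric", df = "integer", pvalue = "numeric"))

setValidity("HetTest", function(object) {
  if (object@Q < 0) return("Q must be nonnegative")
  TRUE
})

#' PressoFit: MR-PRESSO global, outlier and distortion results
#'
#' @slot rssObs observed leave-one-out weighted residual sum of squares.
#' @slot globalP simulation p-value of the global pleiotropy test.
#' @slot outlierP,outlierPAdjusted per-variant empirical tail p-values and
#'   their Bonferroni adjustment.
#' @slot outlierIds variants flagged at `outlierAlpha`.
#' @slot uncorrected,corrected IVW estimates on all instruments and on the
#'   complement of the outliers.
#' @slot distortionP empirical two-sided distortion p-value (`NA` when no
#'   outliers were detected).
#' @slot status `"ok"` or `"no outliers detected"`.
#' @exportClass PressoFit
setClass("PressoFit",
  slots = c(rssObs = "numeric", globalP = "numeric",
            outlierP = "numeric", outlierPAdjusted = "numeric",
            outlierIds = "character", uncorrected = "ANY", corrected = "ANY",
            distortionP = "numeric", nSim = "integer", seed = "ANY",
            status = "character"))

#' LooFit: leave-one-out sensitivity analysis
#'
#' @slot estimates one random-effects IVW estimate per left-out variant.
#' @slot overall the all-instrument estimate used for comparison.
#' @slot maxAbsShift largest absolute shift of the estimate on removal.
#' @exportClass LooFit
setClass("LooFit",
  slots = c(estimates = "data.frame", overall = "MRestimate",
            maxAbsShift = "numeric"))

#' SimConfig: structure of a simulated two-sample dataset
#'
#' @slot J number of instruments (>= 3).
#' @slot seExposure,seOutcome standard errors of the per-allele effect
#'   estimates in the exposure and outcome samples.
#' @slot effectRange range of true per-allele exposure-effect magnitudes.
#' @slot eafRange range of simulated effect-allele frequencies.
#' @slot outcomeScale `"continuous"` or `"log_odds"`.
#' @slot ldBlocks optional `list(size =, r2 =)` LD block structure.
#' @slot propPalindromic fraction of variants given palindromic alleles.
#' @slot nSampleExposure,nSampleOutcome nominal sample sizes (metadata).
#' @exportClass SimConfig
setClass("SimConfig",
  slots = c(J = "integer", seExposure = "numeric", seOutcome = "numeric",
            effectRange = "numeric", eafRange = "numeric",
            outcomeScale = "character", ldBlocks = "list",
            propPalindromic = "numeric",
            nSampleExposure = "numeric", nSampleOutcome = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@J < 3L) msg <- c(msg, "J must be >= 3")
  if (object@seExposure <= 0 || object@seOutcome <= 0)
    msg <- c(msg, "se scales must be positive")
  if (length(object@effectRange) != 2L || any(object@effectRange <= 0) ||
      diff(object@effectRange) < 0)
    msg <- c(msg, "effectRange must be an increasing positive pair")
  if (!object@outcomeScale %in% c("continuous", "log_odds"))
    msg <- c(msg, "outcomeScale must be 'continuous' or 'log_odds'")
  if (object@propPalindromic < 0 || object@propPalindromic > 1)
    msg <- c(msg, "propPalindromic must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SimTruth: generating parameters of a simulation
#'
#' @slot theta true causal effect (outcome units per exposure SD).
#' @slot pleiotropyMode one of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`.
#' @slot muAlpha,sigmaAlpha mean and sd of the pleiotropic effects.
#' @slot propInvalid fraction of instruments given a pleiotropic effect.
#' @slot seed RNG seed (required; the generator has no hidden randomness).
#' @exportClass SimTruth
setClass("SimTruth",
  slots = c(theta = "numeric", pleiotropyMode = "character",
            muAlpha = "numeric", sigmaAlpha = "numeric",
            propInvalid = "numeric", seed = "numeric"))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (!object@pleiotropyMode %in%
      c("none", "balanced", "directional", "inside_violating"))
    msg <- c(msg, "unknown pleiotropy mode")
  if (object@propInvalid < 0 || object@propInvalid > 1)
    msg <- c(msg, "propInvalid must lie in [0, 1]")
  if (!is.finite(object@seed)) msg <- c(msg, "seed is required")
  if (length(msg)) msg else TRUE
})

#' AnalysisConfig: settings for a full pipeline run
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  slots = c(exposures = "list", outcomes = "list", covariates = "list",
            ld = "ANY", pThreshold = "numeric", clumpR2 = "numeric",
            clumpKb = "numeric", outlierAlpha = "numeric", nSim = "integer",
            nBoot = "integer", nDistortion = "integer", seed = "numeric",
            outdir = "character"))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (!length(object@exposures)) msg <- c(msg, "at least one exposure required")
  if (!length(object@outcomes)) msg <- c(msg, "at least one outcome required")
  if (!is.finite(object@seed)) msg <- c(msg, "seed is required")
  if (object@pThreshold <= 0 || object@pThreshold >= 1)
    msg <- c(msg, "pThreshold must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' ResultBundle: all per-pair results of a pipeline run
#'
#' @slot pairs named list (one element per exposure-outcome pair) with
#'   components `instruments`, `harmonized`, `estimates`, `heterogeneity`,
#'   `presso`, `loo`, or an `error` message for failed pairs.
#' @slot settings the thresholds and seeds used.
#' @slot log run log lines.
#' @exportClass ResultBundle
setClass("ResultBundle",
  slots = c(pairs = "list", settings = "list", log = "character"))
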