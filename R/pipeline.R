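#' Configuration for a full two-sample MR analysis
#'
#' Thresholds default to standard practice for this design: instrument
#' p < 5e-8, LD clumping at r2 = 0.001 within 10,000 kb, outlier test at
#' alpha = 0.05.
#'
#' @param exposures named list of [GwasSummary-class] exposures.
#' @param outcomes named list of [GwasSummary-class] outcomes.
#' @param covariates optional named list of [GwasSummary-class] covariates
#'   for multivariable MR.
#' @param ld optional pairwise LD data.frame (see [readLdInfo()]).
#' @param pThreshold,clumpR2,clumpKb instrument-selection thresholds.
#' @param outlierAlpha MR-PRESSO outlier-test level.
#' @param nSim MR-PRESSO simulations; `nBoot` weighted-median bootstraps;
#'   `nDistortion` distortion-test subset draws.
#' @param seed analysis seed (required; every stochastic step derives from
#'   it).
#' @param outdir default output directory for [writeReport()].
#' @return an [AnalysisConfig-class].
#' @export
analysisConfig <- function(exposures, outcomes, covariates = list(),
                           ld = NULL, pThreshold = 5e-8, clumpR2 = 0.001,
                           clumpKb = 10000, outlierAlpha = 0.05,
                           nSim = 1000, nBoot = 1000, nDistortion = 500,
                           seed, outdir = "mr-results") {
  if (missing(seed)) stop("seed is required")
  if (is(exposures, "GwasSummary")) exposures <- list(exposures)
  if (is(outcomes, "GwasSummary")) outcomes <- list(outcomes)
  name_by_trait <- function(lst) {
    if (is.null(names(lst)) || any(!nzchar(names(lst))))
      names(lst) <- vapply(lst, traitName, character(1))
    lst
  }
  new("AnalysisConfig", exposures = name_by_trait(exposures),
      outcomes = name_by_trait(outcomes),
      covariates = name_by_trait(covariates), ld = ld,
      pThreshold = pThreshold, clumpR2 = clumpR2, clumpKb = clumpKb,
      outlierAlpha = outlierAlpha, nSim = as.integer(nSim),
      nBoot = as.integer(nBoot), nDistortion = as.integer(nDistortion),
      seed = seed, outdir = outdir)
}

#' Read an AnalysisConfig from a YAML file
#'
#' Layout: `exposures` / `outcomes` / `covariates` are lists of entries with
#' `name`, `path`, `unit` and an optional `columns` mapping (semantic field:
#' column name); `ld` is an optional path; the remaining keys (`p_threshold`,
#' `clump_r2`, `clump_kb`, `outlier_alpha`, `n_sim`, `n_boot`,
#' `n_distortion`, `seed`, `outdir`) are scalars. Paths are resolved
#' relative to the config file.
#'
#' @param path YAML config path.
#' @return an [AnalysisConfig-class].
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  load_group <- function(entries) {
    out <- lapply(entries, function(e) {
      readSummaryStats(resolve(e$path),
                       columnMap = if (!is.null(e$columns))
                         unlist(e$columns) else NULL,
                       trait = e$name, unit = e$unit %||% "SD")
    })
    names(out) <- vapply(entries, function(e) e$name, character(1))
    out
  }
  exposures <- load_group(y$exposures)
  outcomes <- load_group(y$outcomes)
  covariates <- if (!is.null(y$covariates)) load_group(y$covariates)
                else list()
  ld <- if (!is.null(y$ld)) readLdInfo(resolve(y$ld)) else NULL
  analysisConfig(exposures = exposures, outcomes = outcomes,
                 covariates = covariates, ld = ld,
                 pThreshold = y$p_threshold %||% 5e-8,
                 clumpR2 = y$clump_r2 %||% 0.001,
                 clumpKb = y$clump_kb %||% 10000,
                 outlierAlpha = y$outlier_alpha %||% 0.05,
                 nSim = y$n_sim %||% 1000, nBoot = y$n_boot %||% 1000,
                 nDistortion = y$n_distortion %||% 500,
                 seed = y$seed %||% stop("config must set a seed"),
                 outdir = y$outdir %||% "mr-results")
}

# Multivariable instrument assembly: union of genome-wide-significant
# variants across the exposure and covariate datasets, then one joint clump
# ranked by the minimum p-value across those datasets. Positions/alleles are
# taken from the first dataset carrying each variant.
.assembleMultiInstruments <- function(datasets, pThreshold, ld, clumpR2,
                                      clumpKb) {
  sig <- unlist(lapply(datasets, function(ds) {
    tryCatch(selectSignificant(ds, pThreshold),
             error = function(e) character(0))
  }), use.names = FALSE)
  sig <- unique(sig)
  if (!length(sig)) stop("no instruments across the multivariable datasets")

  rows <- NULL
  minp <- rep(Inf, length(sig))
  for (ds in datasets) {
    idx <- match(sig, ds@data$variant_id)
    hit <- !is.na(idx)
    minp[hit] <- pmin(minp[hit], ds@data$pvalue[idx[hit]])
    if (is.null(rows)) {
      rows <- ds@data[idx, ]
    } else {
      fill <- is.na(rows$variant_id) & hit
      rows[fill, ] <- ds@data[idx[fill], ]
    }
  }
  rows$variant_id <- sig
  rows$pvalue <- pmax(minp, .Machine$double.xmin)
  pseudo <- gwasSummary("multivariable_union", "mixed", rows)
  ldClump(sig, pseudo, ld, clumpR2, clumpKb)
}

.analyzePair <- function(exposure, outcome, config, covariates, pairSeed) {
  ids <- selectSignificant(exposure, config@pThreshold)
  clumped <- ldClump(ids, exposure, config@ld, config@clumpR2,
                     config@clumpKb)
  if (length(clumped) < 3)
    stop("fewer than 3 independent instruments after clumping")
  inst <- instrumentStrength(clumped, exposure,
                             selectionLog = list(
                               n_significant = length(ids),
                               n_clumped = length(clumped)))
  hp <- harmonizePair(exposure, outcome, clumped)
  nkept <- sum(hp@data$action %in% c("kept", "flipped"))
  if (nkept < 3)
    stop("fewer than 3 instruments survive harmonization")

  ivw <- toOddsRatio(mrIVW(hp))
  egger <- toOddsRatio(mrEgger(hp))
  wmed <- toOddsRatio(mrWeightedMedian(hp, nBoot = config@nBoot,
                                       seed = pairSeed))
  presso <- mrPresso(hp, nSim = config@nSim, seed = pairSeed + 1L,
                     outlierAlpha = config@outlierAlpha,
                     nDistortion = config@nDistortion)
  corrected <- toOddsRatio(presso@corrected)

  estimates <- list(IVW = ivw, `PRESSO-corrected` = corrected)
  if (length(covariates)) {
    mvIds <- .assembleMultiInstruments(c(list(exposure), covariates),
                                       config@pThreshold, config@ld,
                                       config@clumpR2, config@clumpKb)
    mh <- harmonizeMulti(c(list(exposure), covariates), outcome, mvIds)
    estimates$MultivariableIVW <- toOddsRatio(mrMultivariable(mh)[[1]])
  }
  estimates$WeightedMedian <- wmed
  estimates$`MR-Egger` <- egger

  list(instruments = inst, harmonized = hp, estimates = estimates,
       heterogeneity = cochranQ(hp), presso = presso,
       loo = leaveOneOut(hp))
}

#' Run the full two-sample MR analysis
#'
#' For every exposure-outcome pair: instrument selection, LD clumping,
#' harmonization, the five causal estimators (IVW, MR-PRESSO-corrected,
#' multivariable IVW when covariates are configured, weighted median,
#' MR-Egger), Cochran's Q, the MR-PRESSO battery and leave-one-out. Pairs
#' run independently: a failure in one pair is recorded as that pair's
#' `error` and the run continues. Deterministic given the config seed.
#'
#' @param config an [AnalysisConfig-class].
#' @return a [ResultBundle-class].
#' @export
runAnalysis <- function(config) {
  stopifnot(is(config, "AnalysisConfig"))
  validObject(config)
  pairs <- list()
  log <- c(sprintf("mrkit %s run, seed %d",
                   as.character(utils::packageVersion("mrkit")),
                   as.integer(config@seed)),
           sprintf("thresholds: p<%g, clump r2=%g within %g kb, outlier alpha=%g",
                   config@pThreshold, config@clumpR2, config@clumpKb,
                   config@outlierAlpha),
           sprintf("nSim=%d nBoot=%d nDistortion=%d", config@nSim,
                   config@nBoot, config@nDistortion))
  k <- 0L
  for (en in names(config@exposures)) {
    for (on in names(config@outcomes)) {
      k <- k + 1L
      key <- paste(en, on, sep = " -> ")
      pairSeed <- as.integer((config@seed + 7919 * k) %% (2^31 - 1))
      res <- tryCatch(
        .analyzePair(config@exposures[[en]], config@outcomes[[on]],
                     config, config@covariates, pairSeed),
        error = function(e) list(error = conditionMessage(e)))
      res$exposure <- en
      res$outcome <- on
      pairs[[key]] <- res
      log <- c(log, if (!is.null(res$error))
        sprintf("pair %s: FAILED (%s)", key, res$error)
      else
        sprintf("pair %s: %d instruments, %d harmonized, %d PRESSO outliers",
                key, length(res$instruments@variantIds),
                sum(res$harmonized@data$action %in% c("kept", "flipped")),
                length(res$presso@outlierIds)))
    }
  }
  new("ResultBundle", pairs = pairs,
      settings = list(pThreshold = config@pThreshold,
                      clumpR2 = config@clumpR2, clumpKb = config@clumpKb,
                      outlierAlpha = config@outlierAlpha,
                      nSim = config@nSim, nBoot = config@nBoot,
                      nDistortion = config@nDistortion, seed = config@seed,
                      exposures = names(config@exposures),
                      outcomes = names(config@outcomes),
                      covariates = names(config@covariates)),
      log = log)
}

setMethod("show", "ResultBundle", function(object) {
  ok <- vapply(object@pairs, function(p) is.null(p$error), logical(1))
  cat("ResultBundle:", length(object@pairs), "pair(s),",
      sum(!ok), "failed\n")
  for (nm in names(object@pairs)) {
    p <- object@pairs[[nm]]
    if (!is.null(p$error)) {
      cat("  ", nm, ": ERROR -", p$error, "\n")
    } else {
      cat(sprintf("  %s: IVW beta %.4f (p %.3g), %d methods\n", nm,
                  p$estimates$IVW@beta, p$estimates$IVW@pvalue,
                  length(p$estimates)))
    }
  }
})
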