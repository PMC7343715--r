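#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_j (ratio_j - beta_IVW)^2` with fixed-effect weights
#' `w_j = 1 / se_ratio_j^2` and the fixed-effect IVW pooled estimate;
#' referred to the chi-square distribution with J - 1 df. Excess Q signals
#' heterogeneity between instruments, the usual footprint of horizontal
#' pleiotropy.
#'
#' @inheritParams waldRatio
#' @return a [HetTest-class].
#' @export
cochranQ <- function(x, seOrder = c("first", "second")) {
  r <- waldRatio(x, seOrder)
  J <- nrow(r)
  if (J < 2) stop("insufficient instruments: Q requires >= 2 records")
  core <- .ivw_core(r$ratio, r$weight)
  new("HetTest", Q = core$Q, df = J - 1L,
      pvalue = stats::pchisq(core$Q, J - 1, lower.tail = FALSE))
}

# Shared PRESSO machinery. Returns observed leave-one-out residuals/RSS and
# the simulated null distributions, all under weights 1/se_Gamma^2.
# Simulated datasets are drawn from the fitted no-pleiotropy model:
# gamma* ~ N(gamma, se_gamma), Gamma* ~ N(beta_(-j) * gamma, se_Gamma).
.presso_core <- function(d, nSim, seed) {
  J <- nrow(d)
  w <- 1 / d$se_Gamma^2
  g <- d$gamma
  G <- d$Gamma

  loo_slope <- function(gv, Gv, wv) {
    Sn <- sum(wv * gv * Gv)
    Sd <- sum(wv * gv^2)
    (Sn - wv * gv * Gv) / (Sd - wv * gv^2)
  }
  bLoo <- loo_slope(g, G, w)
  res_obs <- G - bLoo * g
  rss_obs <- sum(w * res_obs^2)

  sims <- .withSeed(seed, function() {
    gS <- matrix(stats::rnorm(nSim * J, mean = rep(g, each = nSim),
                              sd = rep(d$se_gamma, each = nSim)),
                 nrow = nSim)
    GS <- matrix(stats::rnorm(nSim * J, mean = rep(bLoo * g, each = nSim),
                              sd = rep(d$se_Gamma, each = nSim)),
                 nrow = nSim)
    Wm <- matrix(w, nSim, J, byrow = TRUE)
    SnS <- rowSums(Wm * gS * GS)
    SdS <- rowSums(Wm * gS^2)
    bLooS <- (SnS - Wm * gS * GS) / (SdS - Wm * gS^2)
    resS <- GS - bLooS * gS
    wres2 <- Wm * resS^2
    list(rss = rowSums(wres2), wres2 = wres2)
  })
  list(J = J, w = w, rss_obs = rss_obs, wres2_obs = w * res_obs^2,
       rss_sim = sims$rss, wres2_sim = sims$wres2)
}

#' MR-PRESSO global pleiotropy test
#'
#' The observed residual sum of squares is computed with leave-one-out
#' slopes: each variant's weighted squared residual about
#' `beta_(-j) * gamma_j`, where `beta_(-j)` is the fixed-effect IVW slope
#' excluding variant j. Its null distribution is obtained by parametric
#' simulation from the fitted no-pleiotropy model, and
#' `global_p = (1 + #\{RSS* >= RSS_obs\}) / (nSim + 1)`.
#'
#' @inheritParams waldRatio
#' @param nSim number of parametric simulations (default 1000).
#' @param seed seed for the simulations (`NULL` = current RNG stream).
#' @return list with elements `rssObs`, `globalP`, `nSim`.
#' @export
pressoGlobal <- function(x, nSim = 1000, seed = NULL) {
  d <- .hdata(x)
  if (nrow(d) < 4)
    stop("insufficient instruments: MR-PRESSO requires >= 4 records")
  core <- .presso_core(d, nSim, seed)
  list(rssObs = core$rss_obs,
       globalP = (1 + sum(core$rss_sim >= core$rss_obs)) / (nSim + 1),
       nSim = nSim)
}

#' MR-PRESSO outlier and distortion tests
#'
#' Extends the global test with a per-variant outlier test (each observed
#' weighted squared residual against its own simulated distribution,
#' Bonferroni-adjusted across instruments) and a distortion test. Flagged
#' outliers are removed and the IVW estimate recomputed on the complement;
#' the distortion p-value is the empirical probability that removing a
#' random subset of the same size shifts the estimate at least as much as
#' outlier removal did. When no outlier is flagged, the corrected estimate
#' equals the full-set IVW, the status is `"no outliers detected"` and the
#' distortion p is `NA`.
#'
#' The minimum attainable Bonferroni-adjusted p is `J / (nSim + 1)`; a
#' warning is emitted when that floor exceeds `outlierAlpha` (the outlier
#' test then has no resolution and `nSim` should be raised).
#'
#' @inheritParams pressoGlobal
#' @param outlierAlpha significance level for the adjusted outlier test
#'   (default 0.05).
#' @param nDistortion number of random same-size subset removals for the
#'   distortion test (default 500).
#' @param model IVW model for the uncorrected/corrected estimates.
#' @return a [PressoFit-class].
#' @export
mrPresso <- function(x, nSim = 1000, seed = NULL, outlierAlpha = 0.05,
                     nDistortion = 500, model = c("random", "fixed", "dl")) {
  model <- match.arg(model)
  d <- .hdata(x)
  J <- nrow(d)
  if (J < 4)
    stop("insufficient instruments: MR-PRESSO requires >= 4 records")
  if (J / (nSim + 1) >= outlierAlpha)
    warning("nSim too small for the Bonferroni outlier test: minimum ",
            "adjusted p = ", format(J / (nSim + 1), digits = 3),
            " >= outlierAlpha; no outlier can be flagged")

  core <- .presso_core(d, nSim, seed)
  globalP <- (1 + sum(core$rss_sim >= core$rss_obs)) / (nSim + 1)

  exceed <- colSums(core$wres2_sim >=
                    matrix(core$wres2_obs, nSim, J, byrow = TRUE))
  pRaw <- (1 + exceed) / (nSim + 1)
  pAdj <- pmin(1, J * pRaw)
  names(pRaw) <- names(pAdj) <- d$variant_id
  outliers <- d$variant_id[pAdj < outlierAlpha]

  meta <- .pair_meta(x)
  full <- mrIVW(d, model = model)
  full@exposure <- meta$exposure
  full@outcome <- meta$outcome
  full@outcomeUnit <- meta$outcomeUnit

  if (length(outliers) == 0) {
    corrected <- full
    corrected@method <- "PRESSO-corrected"
    return(new("PressoFit", rssObs = core$rss_obs, globalP = globalP,
               outlierP = pRaw, outlierPAdjusted = pAdj,
               outlierIds = character(0), uncorrected = full,
               corrected = corrected, distortionP = NA_real_,
               nSim = as.integer(nSim), seed = seed,
               status = "no outliers detected"))
  }
  keep <- !(d$variant_id %in% outliers)
  if (sum(keep) < 2)
    stop("degenerate correction: fewer than 2 instruments remain after ",
         "outlier removal")
  corrected <- mrIVW(d[keep, , drop = FALSE], model = model)
  corrected@method <- "PRESSO-corrected"
  corrected@exposure <- meta$exposure
  corrected@outcome <- meta$outcome
  corrected@outcomeUnit <- meta$outcomeUnit

  # Distortion: how unusual is the observed shift compared with removing a
  # random subset of the same size?
  m <- length(outliers)
  w <- 1 / d$se_Gamma^2
  num <- w * d$gamma * d$Gamma
  den <- w * d$gamma^2
  Sn <- sum(num)
  Sd <- sum(den)
  dObs <- abs(corrected@beta - full@beta)
  shifts <- .withSeed(if (is.null(seed)) NULL else seed + 1L, function() {
    vapply(seq_len(nDistortion), function(b) {
      idx <- sample.int(J, m)
      abs((Sn - sum(num[idx])) / (Sd - sum(den[idx])) - full@beta)
    }, numeric(1))
  })
  distortionP <- (1 + sum(shifts >= dObs)) / (nDistortion + 1)

  new("PressoFit", rssObs = core$rss_obs, globalP = globalP,
      outlierP = pRaw, outlierPAdjusted = pAdj, outlierIds = outliers,
      uncorrected = full, corrected = corrected, distortionP = distortionP,
      nSim = as.integer(nSim), seed = seed, status = "ok")
}

#' Leave-one-out sensitivity analysis
#'
#' The random-effects IVW is repeated leaving out each instrument in turn;
#' the overall all-instrument estimate is the comparator. A large
#' `maxAbsShift` indicates that a single variant disproportionately drives
#' the pooled estimate.
#'
#' @inheritParams waldRatio
#' @param model IVW model (default `"random"`, matching the headline
#'   analysis).
#' @return a [LooFit-class] with exactly J leave-one-out estimates.
#' @export
leaveOneOut <- function(x, model = c("random", "fixed", "dl")) {
  model <- match.arg(model)
  d <- .hdata(x)
  J <- nrow(d)
  if (J < 3)
    stop("insufficient instruments: leave-one-out requires >= 3 records")
  overall <- mrIVW(d, model = model)
  meta <- .pair_meta(x)
  overall@exposure <- meta$exposure
  overall@outcome <- meta$outcome
  overall@outcomeUnit <- meta$outcomeUnit

  rows <- lapply(seq_len(J), function(j) {
    e <- mrIVW(d[-j, , drop = FALSE], model = model)
    data.frame(excluded = d$variant_id[j], beta = e@beta, se = e@se,
               ciLow = e@ciLow, ciHigh = e@ciHigh, pvalue = e@pvalue,
               stringsAsFactors = FALSE)
  })
  est <- do.call(rbind, rows)
  new("LooFit", estimates = est, overall = overall,
      maxAbsShift = max(abs(est$beta - overall@beta)))
}

## show methods ----------------------------------------------------------

setMethod("show", "HetTest", function(object) {
  cat(sprintf("Cochran's Q = %.3f, df = %d, p = %.3g\n",
              object@Q, object@df, object@pvalue))
})

setMethod("show", "PressoFit", function(object) {
  cat("MR-PRESSO\n")
  cat(sprintf("  global test: RSSobs = %.3f, p = %.3g (nSim = %d)\n",
              object@rssObs, object@globalP, object@nSim))
  cat(sprintf("  outliers: %d flagged%s\n", length(object@outlierIds),
              if (object@status == "no outliers detected")
                " (no outliers detected)" else ""))
  if (is.finite(object@distortionP))
    cat(sprintf("  distortion p = %.3g\n", object@distortionP))
  if (is(object@corrected, "MRestimate"))
    cat(sprintf("  corrected beta = %.4f (full-set beta = %.4f)\n",
                object@corrected@beta, object@uncorrected@beta))
})

setMethod("show", "LooFit", function(object) {
  cat(sprintf("Leave-one-out: %d estimates, overall beta = %.4f, max |shift| = %.4g\n",
              nrow(object@estimates), object@overall@beta,
              object@maxAbsShift))
})
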