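#' Per-variant Wald ratios
#'
#' The ratio estimate for each variant is the outcome effect divided by the
#' exposure effect, `Gamma / gamma`. The first-order delta-method standard
#' error is `se_Gamma / |gamma|`; the second-order form adds the term from
#' the exposure-side sampling noise,
#' `sqrt(se_Gamma^2 / gamma^2 + Gamma^2 * se_gamma^2 / gamma^4)`.
#'
#' @param x a [HarmonizedPair-class] or a data.frame with columns `gamma`,
#'   `se_gamma`, `Gamma`, `se_Gamma` (and optionally `variant_id`).
#' @param seOrder `"first"` (default) or `"second"` order delta-method se.
#' @return data.frame with columns `variant_id`, `ratio`, `se_ratio`,
#'   `weight` (= 1 / se_ratio^2).
#' @export
waldRatio <- function(x, seOrder = c("first", "second")) {
  seOrder <- match.arg(seOrder)
  d <- .hdata(x)
  if (any(d$gamma == 0))
    stop("degenerate instrument: gamma = 0 for ",
         paste(head(d$variant_id[d$gamma == 0], 5), collapse = ", "))
  ratio <- d$Gamma / d$gamma
  se <- if (seOrder == "first") {
    d$se_Gamma / abs(d$gamma)
  } else {
    sqrt(d$se_Gamma^2 / d$gamma^2 + d$Gamma^2 * d$se_gamma^2 / d$gamma^4)
  }
  data.frame(variant_id = d$variant_id, ratio = ratio, se_ratio = se,
             weight = 1 / se^2, stringsAsFactors = FALSE)
}

# Fixed-effect IVW pooled estimate from ratios; shared by several callers.
.ivw_core <- function(ratio, weight) {
  beta <- sum(weight * ratio) / sum(weight)
  seF <- sqrt(1 / sum(weight))
  Q <- sum(weight * (ratio - beta)^2)
  list(beta = beta, seF = seF, Q = Q)
}

#' Inverse-variance weighted causal estimate
#'
#' Wald ratios are pooled with inverse-variance weights:
#' `beta = sum(w_j r_j) / sum(w_j)` with `w_j = 1 / se_ratio_j^2`. With
#' first-order ratio standard errors this is identical to weighted least
#' squares of the outcome effects on the exposure effects through the origin
#' with weights `1 / se_Gamma^2`.
#'
#' The default `"random"` model is multiplicative random effects: the fixed
#' standard error `(sum w_j)^(-1/2)` is inflated by
#' `sqrt(max(1, Q / (J - 1)))`, so under homogeneity it reduces to the fixed
#' model. `"dl"` is additive DerSimonian-Laird random effects. P-values are
#' two-sided from the normal reference; 95% CIs use the normal quantile.
#'
#' @inheritParams waldRatio
#' @param model `"random"` (multiplicative, default), `"fixed"`, or `"dl"`.
#' @return an [MRestimate-class] (method `"IVW"`).
#' @export
mrIVW <- function(x, model = c("random", "fixed", "dl"),
                  seOrder = c("first", "second")) {
  model <- match.arg(model)
  r <- waldRatio(x, seOrder)
  J <- nrow(r)
  if (J < 2) stop("insufficient instruments: IVW requires >= 2 records")
  core <- .ivw_core(r$ratio, r$weight)
  beta <- core$beta
  se <- switch(model,
    fixed = core$seF,
    random = core$seF * sqrt(max(1, core$Q / (J - 1))),
    dl = {
      w <- r$weight
      tau2 <- max(0, (core$Q - (J - 1)) / (sum(w) - sum(w^2) / sum(w)))
      w2 <- 1 / (r$se_ratio^2 + tau2)
      beta <- sum(w2 * r$ratio) / sum(w2)
      sqrt(1 / sum(w2))
    })
  meta <- .pair_meta(x)
  .mkEstimate(method = "IVW", beta = beta, se = se,
              pvalue = .z2p(beta / se),
              ciLow = beta - .CI_Z * se, ciHigh = beta + .CI_Z * se,
              nsnp = J, meta = meta,
              details = list(model = model, Q = core$Q, seFixed = core$seF))
}

#' MR-Egger regression
#'
#' Records are first oriented so that every exposure effect is nonnegative
#' (both effects of a record are negated when `gamma < 0`), then the outcome
#' effects are regressed on the exposure effects *with* an intercept, using
#' weights `1 / se_Gamma^2`. The slope is the pleiotropy-corrected causal
#' estimate; an intercept significantly different from zero (P < 0.05 by
#' convention) indicates directional horizontal pleiotropy or an InSIDE
#' violation. Standard errors carry the multiplicative overdispersion factor
#' floored at 1; inference uses the t distribution with J - 2 df by default.
#'
#' @inheritParams waldRatio
#' @param inference `"t"` (default) or `"normal"` reference for p-values/CIs.
#' @return an [MRestimate-class] (method `"MR-Egger"`) with intercept slots.
#' @export
mrEgger <- function(x, inference = c("t", "normal")) {
  inference <- match.arg(inference)
  d <- .hdata(x)
  J <- nrow(d)
  if (J < 3) stop("insufficient instruments: MR-Egger requires >= 3 records")
  s <- ifelse(d$gamma < 0, -1, 1)
  g <- d$gamma * s
  G <- d$Gamma * s
  if (stats::var(g) == 0)
    stop("collinearity: zero variance in exposure effects")
  w <- 1 / d$se_Gamma^2

  X <- cbind(intercept = 1, slope = g)
  XtWX <- crossprod(X, w * X)
  coefs <- drop(solve(XtWX, crossprod(X, w * G)))
  resid <- G - drop(X %*% coefs)
  rss <- sum(w * resid^2)
  mult <- max(1, sqrt(rss / (J - 2)))
  ses <- sqrt(diag(solve(XtWX))) * mult

  q <- if (inference == "t") stats::qt(0.975, J - 2) else .CI_Z
  pfun <- if (inference == "t") {
    function(est, se) 2 * stats::pt(-abs(est / se), J - 2)
  } else {
    function(est, se) .z2p(est / se)
  }
  meta <- .pair_meta(x)
  b <- unname(coefs["slope"])
  bse <- unname(ses["slope"])
  a <- unname(coefs["intercept"])
  ase <- unname(ses["intercept"])
  .mkEstimate(method = "MR-Egger",
              beta = b, se = bse, pvalue = pfun(b, bse),
              ciLow = b - q * bse, ciHigh = b + q * bse,
              nsnp = J, meta = meta,
              intercept = a, seIntercept = ase,
              interceptCiLow = a - q * ase, interceptCiHigh = a + q * ase,
              pIntercept = pfun(a, ase),
              details = list(inference = inference, rss = rss, mult = mult))
}

# Weighted median of values x with weights w: sort ascending, place each
# value at the midpoint of its cumulative normalized weight, and linearly
# interpolate to the 0.5 position.
.weightedMedian <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(x[1])
  n <- length(x)
  if (0.5 >= s[n]) return(x[n])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted median causal estimate
#'
#' The weighted median of the per-variant Wald ratios (weights
#' `1 / se_ratio^2`), consistent when instruments carrying at least half the
#' weight are valid. The standard error comes from a parametric bootstrap:
#' each ratio is resampled from a normal centred on its estimate with its
#' standard error and the weighted median recomputed.
#'
#' @inheritParams waldRatio
#' @param nBoot bootstrap replicates for the se (default 1000; a value below
#'   100 triggers a warning; 0 skips the bootstrap, leaving se/CI/p `NA`).
#' @param seed optional seed for the bootstrap; `NULL` uses the current RNG
#'   stream.
#' @return an [MRestimate-class] (method `"WeightedMedian"`).
#' @export
mrWeightedMedian <- function(x, nBoot = 1000, seed = NULL,
                             seOrder = c("first", "second")) {
  r <- waldRatio(x, seOrder)
  J <- nrow(r)
  if (J < 3)
    stop("insufficient instruments: weighted median requires >= 3 records")
  beta <- .weightedMedian(r$ratio, r$weight)
  se <- NA_real_
  if (nBoot > 0) {
    if (nBoot < 100)
      warning("nBoot < 100: bootstrap standard error will be unstable")
    boots <- .withSeed(seed, function() {
      draws <- matrix(stats::rnorm(J * nBoot, mean = r$ratio,
                                   sd = r$se_ratio), nrow = J)
      apply(draws, 2, .weightedMedian, w = r$weight)
    })
    se <- stats::sd(boots)
  }
  meta <- .pair_meta(x)
  .mkEstimate(method = "WeightedMedian", beta = beta, se = se,
              pvalue = if (is.na(se)) NA_real_ else .z2p(beta / se),
              ciLow = if (is.na(se)) NA_real_ else beta - .CI_Z * se,
              ciHigh = if (is.na(se)) NA_real_ else beta + .CI_Z * se,
              nsnp = J, meta = meta, details = list(nBoot = nBoot))
}

#' Multivariable IVW
#'
#' Weighted least squares of the outcome effects on all exposure-effect
#' columns jointly, without intercept, weights `1 / se_Gamma^2`. Each
#' exposure's coefficient is its direct effect conditional on the others.
#' Standard errors carry the multiplicative overdispersion factor floored at
#' 1 (`model = "random"`, the default) or not (`"fixed"`); with a single
#' exposure column the estimate reduces to univariable IVW.
#'
#' @param x a [HarmonizedMulti-class], or a data.frame with columns
#'   `gamma_<name>` (one per exposure), `Gamma` and `se_Gamma`.
#' @param model `"random"` (default) or `"fixed"`.
#' @return list of [MRestimate-class] (method `"MultivariableIVW"`), one per
#'   exposure, named by exposure.
#' @export
mrMultivariable <- function(x, model = c("random", "fixed")) {
  model <- match.arg(model)
  if (is(x, "HarmonizedMulti")) {
    d <- x@data
    traits <- x@exposures
    meta0 <- list(outcome = x@outcome, outcomeUnit = x@outcomeUnit)
  } else {
    d <- as.data.frame(x)
    gcols <- grep("^gamma_", names(d), value = TRUE)
    gcols <- setdiff(gcols, grep("^se_gamma_", names(d), value = TRUE))
    traits <- sub("^gamma_", "", gcols)
    meta0 <- list(outcome = "", outcomeUnit = "")
  }
  gcols <- paste0("gamma_", traits)
  miss <- setdiff(c(gcols, "Gamma", "se_Gamma"), names(d))
  if (length(miss))
    stop("multivariable table lacks columns: ", paste(miss, collapse = ", "))
  if (!length(traits)) stop("no exposure-effect columns found")

  X <- as.matrix(d[, gcols, drop = FALSE])
  y <- d$Gamma
  w <- 1 / d$se_Gamma^2
  n <- nrow(X)
  k <- ncol(X)
  if (n < k + 1)
    stop("insufficient instruments: need more variants than exposures")
  XtWX <- crossprod(X, w * X)
  if (qr(XtWX)$rank < k)
    stop("rank deficiency: exposure effect columns are collinear")
  coefs <- drop(solve(XtWX, crossprod(X, w * y)))
  resid <- y - drop(X %*% coefs)
  rss <- sum(w * resid^2)
  mult <- if (model == "random") max(1, sqrt(rss / (n - k))) else 1
  ses <- sqrt(diag(solve(XtWX))) * mult

  out <- lapply(seq_len(k), function(j) {
    .mkEstimate(method = "MultivariableIVW", beta = unname(coefs[j]),
                se = unname(ses[j]), pvalue = .z2p(coefs[j] / ses[j]),
                ciLow = unname(coefs[j] - .CI_Z * ses[j]),
                ciHigh = unname(coefs[j] + .CI_Z * ses[j]),
                nsnp = n,
                meta = list(exposure = traits[j],
                            outcome = meta0$outcome,
                            outcomeUnit = meta0$outcomeUnit),
                details = list(model = model, rss = rss,
                               exposures = traits))
  })
  names(out) <- traits
  out
}

#' Report an estimate on the exponentiated (odds-ratio) scale
#'
#' Fills the `or`, `orLow`, `orHigh` slots with `exp(beta)` and the
#' exponentiated CI bounds. For log-odds outcomes this is the odds ratio per
#' SD of exposure; for log-scaled or standardized continuous traits it is
#' the conventionally reported exponentiated effect.
#'
#' @param estimate an [MRestimate-class].
#' @return the estimate with the exponentiated-scale slots filled.
#' @export
toOddsRatio <- function(estimate) {
  stopifnot(is(estimate, "MRestimate"))
  estimate@or <- exp(estimate@beta)
  estimate@orLow <- exp(estimate@ciLow)
  estimate@orHigh <- exp(estimate@ciHigh)
  estimate
}

## Accessors / show ------------------------------------------------------

#' @rdname accessors
setMethod("mrMethod", "MRestimate", function(x) x@method)
#' @rdname accessors
setMethod("mrBeta", "MRestimate", function(x) x@beta)
#' @rdname accessors
setMethod("mrSE", "MRestimate", function(x) x@se)
#' @rdname accessors
setMethod("mrCI", "MRestimate", function(x) c(x@ciLow, x@ciHigh))
#' @rdname accessors
setMethod("mrPvalue", "MRestimate", function(x) x@pvalue)
#' @rdname accessors
setMethod("mrNsnp", "MRestimate", function(x) x@nsnp)
#' @rdname accessors
setMethod("mrOR", "MRestimate", function(x)
  c(or = x@or, low = x@orLow, high = x@orHigh))
#' @rdname accessors
setMethod("mrIntercept", "MRestimate", function(x)
  c(intercept = x@intercept, se = x@seIntercept, p = x@pIntercept))

setMethod("show", "MRestimate", function(object) {
  cat(sprintf("MRestimate [%s]%s\n", object@method,
              if (nzchar(object@exposure))
                sprintf(" %s -> %s", object@exposure, object@outcome)
              else ""))
  cat(sprintf("  beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g, nSNP = %d\n",
              object@beta, object@se, object@ciLow, object@ciHigh,
              object@pvalue, object@nsnp))
  if (is.finite(object@or))
    cat(sprintf("  exp scale: %.3f (%.3f, %.3f)\n",
                object@or, object@orLow, object@orHigh))
  if (is.finite(object@intercept))
    cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g\n",
                object@intercept, object@seIntercept, object@pIntercept))
})
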