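# Internal helpers.

#' @import methods
#' @importFrom stats pnorm qnorm pchisq pt qt rnorm runif sd approx ks.test
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.CI_Z <- stats::qnorm(0.975)

# Run fun() under a temporary seed, restoring the caller's RNG state.
# seed = NULL means "use the current stream" (still reproducible under an
# outer set.seed()).
.withSeed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fun()
}

# Two-sided p from an exact z-score, floored at a representable positive
# value so the (0, 1] invariant survives underflow at |z| > ~39.
.z2p <- function(z) pmax(2 * stats::pnorm(-abs(z)), 1e-300)

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Extract the estimation-ready records from a HarmonizedPair or a plain
# data.frame with columns gamma, se_gamma, Gamma, se_Gamma (+ variant_id).
.hdata <- function(x) {
  if (is(x, "HarmonizedPair")) {
    d <- x@data[x@data$action %in% c("kept", "flipped"), , drop = FALSE]
  } else {
    d <- as.data.frame(x)
  }
  need <- c("gamma", "se_gamma", "Gamma", "se_Gamma")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("harmonized records lack columns: ", paste(miss, collapse = ", "))
  if (is.null(d$variant_id)) d$variant_id <- paste0("v", seq_len(nrow(d)))
  if (any(d$se_gamma <= 0) || any(d$se_Gamma <= 0))
    stop("standard errors must be positive")
  d
}

.pair_meta <- function(x) {
  if (is(x, "HarmonizedPair"))
    list(exposure = x@exposure, outcome = x@outcome,
         outcomeUnit = x@outcomeUnit)
  else
    list(exposure = "", outcome = "", outcomeUnit = "")
}

.mkEstimate <- function(method, beta, se, pvalue, ciLow, ciHigh, nsnp,
                        meta = list(exposure = "", outcome = "",
                                    outcomeUnit = ""),
                        intercept = NA_real_, seIntercept = NA_real_,
                        interceptCiLow = NA_real_, interceptCiHigh = NA_real_,
                        pIntercept = NA_real_, details = list()) {
  new("MRestimate", method = method,
      exposure = meta$exposure, outcome = meta$outcome,
      outcomeUnit = meta$outcomeUnit,
      beta = beta, se = se, ciLow = ciLow, ciHigh = ciHigh,
      pvalue = pvalue, nsnp = as.integer(nsnp),
      or = NA_real_, orLow = NA_real_, orHigh = NA_real_,
      intercept = intercept, seIntercept = seIntercept,
      interceptCiLow = interceptCiLow, interceptCiHigh = interceptCiHigh,
      pIntercept = pIntercept, details = details)
}
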