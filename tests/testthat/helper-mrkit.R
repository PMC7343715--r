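# Fixture builders shared across test files. All fixtures are constructed in
# code; no data files.

make_variant_df <- function(id, ea, oa, beta, se, pvalue = NULL, eaf = NA,
                            chrom = "1", pos = NULL, n = NA) {
  if (is.null(pvalue)) pvalue <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  if (is.null(pos)) pos <- seq_along(id) * 1e5
  data.frame(variant_id = id, chrom = chrom, pos = pos, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se,
             pvalue = pvalue, n = n, stringsAsFactors = FALSE)
}

make_gwas <- function(..., trait = "trait", unit = "SD") {
  gwasSummary(trait, unit, make_variant_df(...))
}

# Plain harmonized-record frame, the light-weight input the estimators accept.
hframe <- function(gamma, se_gamma, Gamma, se_Gamma,
                   id = paste0("v", seq_along(gamma))) {
  data.frame(variant_id = id, gamma = gamma, se_gamma = se_gamma,
             Gamma = Gamma, se_Gamma = se_Gamma, stringsAsFactors = FALSE)
}

# Random harmonized instance for oracle tests (positive exposure effects,
# arbitrary outcome effects, heteroscedastic ses).
rand_hframe <- function(J) {
  hframe(gamma = runif(J, 0.02, 0.2),
         se_gamma = runif(J, 0.002, 0.01),
         Gamma = rnorm(J, 0, 0.1),
         se_Gamma = runif(J, 0.005, 0.05))
}

# Independent long-hand weighted median: explicit cumulative-midpoint loop
# and manual linear interpolation (oracle for mrWeightedMedian).
bf_weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w[ord])
  s <- numeric(length(x))
  acc <- 0
  for (j in seq_along(x)) {
    s[j] <- acc + w[j] / 2
    acc <- acc + w[j]
  }
  if (0.5 <= s[1]) return(x[1])
  if (0.5 >= s[length(x)]) return(x[length(x)])
  j <- max(which(s < 0.5))
  x[j] + (x[j + 1] - x[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}
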