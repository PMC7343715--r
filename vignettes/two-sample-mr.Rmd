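---
title: "Two-sample Mendelian randomization with mrkit: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables. For variant $j$, one GWAS estimates its per-allele effect on the
exposure, $\hat\gamma_j \sim N(\gamma_j, \sigma_{xj}^2)$, and an independent
GWAS estimates its effect on the outcome,
$\hat\Gamma_j \sim N(\Gamma_j, \sigma_{yj}^2)$. Under the instrumental-variable
assumptions (association with the exposure; independence of confounders;
effect on the outcome only through the exposure) the structural model is

$$\Gamma_j = \theta\,\gamma_j + \alpha_j,$$

where $\theta$ is the causal effect per unit (here: SD) of exposure and
$\alpha_j$ is variant $j$'s *horizontal-pleiotropy* direct effect — zero for
a valid instrument. Each variant supplies a Wald ratio
$\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ with first-order standard error
$\sigma_{yj}/|\hat\gamma_j|$ (a second-order form adding the
exposure-noise term is available via `seOrder = "second"`).

The estimators differ in what they assume about the $\alpha_j$:

* **IVW** (`mrIVW`) pools ratios with weights $w_j = 1/\mathrm{se}(\hat\beta_j)^2$,
  which with first-order ratio errors is exactly weighted least squares of
  $\hat\Gamma$ on $\hat\gamma$ through the origin with weights
  $1/\sigma_{yj}^2$ — consistent only when pleiotropy is absent or balanced
  with weights uncorrelated with $\alpha_j$.
* **MR-Egger** (`mrEgger`) frees the intercept: after orienting every record
  to $\hat\gamma_j \ge 0$, it regresses $\hat\Gamma$ on $\hat\gamma$ *with*
  intercept. Under the InSIDE assumption (direct effects independent of
  instrument strength) the slope is consistent for $\theta$ and the
  intercept estimates the mean directional pleiotropic effect; an intercept
  with $P < 0.05$ is the conventional pleiotropy flag.
* **Weighted median** (`mrWeightedMedian`) takes the weighted median of the
  ratios (cumulative-weight-midpoint interpolation at 0.5) and is consistent
  whenever valid instruments carry more than half the weight; its standard
  error comes from a parametric bootstrap of the ratios.
* **Multivariable IVW** (`mrMultivariable`) regresses $\hat\Gamma$ jointly
  on the instruments' effects on the exposure *and* on measured covariates
  (no intercept, weights $1/\sigma_{yj}^2$), targeting the direct effect of
  the exposure when pleiotropy acts through those covariates.
* **MR-PRESSO** (`mrPresso`) computes each variant's weighted squared
  residual about the leave-one-out IVW slope; a parametric simulation from
  the fitted no-pleiotropy model gives the null distribution of the residual
  sum (global test), per-variant empirical outlier p-values
  (Bonferroni-adjusted), an IVW estimate corrected by removing outliers, and
  a distortion test comparing that correction with random same-size
  removals.

Heterogeneity among ratios is measured by Cochran's
$Q=\sum_j w_j(\hat\beta_j-\hat\beta_{IVW})^2$ on $J-1$ df
(`cochranQ`), and single-variant influence by leave-one-out IVW
(`leaveOneOut`).

## Tunable parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| Instrument p-value threshold | $5\times10^{-8}$, strict `<` | conventional genome-wide significance |
| Clumping r², window | 0.001 within 10,000 kb | standard stringent instrument pruning |
| Weak-instrument flag | $F \le 10$, flagged not removed | the usual adequacy convention; removal is left to the analyst |
| Palindromic ambiguity window | EAF in [0.42, 0.58] | A/T and C/G variants cannot be strand-resolved from labels; frequencies this close to 0.5 cannot resolve them either, so such records are dropped. Outside the window, alignment follows frequency concordance |
| IVW model | multiplicative random effects, $\mathrm{se}\times\sqrt{\max(1, Q/(J-1))}$ | never less conservative than fixed effects; `"fixed"` and additive DerSimonian–Laird (`"dl"`) are options |
| Egger inference | $t$ with $J-2$ df | small-sample honest; `"normal"` available |
| Bootstrap / simulation sizes | `nBoot = 1000`, `nSim = 1000`, `nDistortion = 500` | stable second digits at interactive cost; all seeded, no hidden randomness |

Empirical p-values use the $(1+k)/(n+1)$ estimator, so they are never
exactly zero. The Bonferroni-adjusted outlier p cannot fall below
$J/(n_{sim}+1)$; `mrPresso` warns when that floor exceeds the outlier
alpha — with $J=100$ instruments the default 1000 simulations cannot flag
anything and $n_{sim} = 5000$ or more is needed.

## The synthetic-data generator

`simulateSummaryStats` works directly on the summary-statistic scale: true
effects $\gamma_j \sim U(0.02, 0.10)$ SD per allele, oriented to the
trait-increasing allele; $\alpha_j$ per the chosen pleiotropy mode (zero;
mean-zero normal; mean `muAlpha`; or correlated ~0.8 with $\gamma_j$ to
violate InSIDE), applied to a `propInvalid` fraction of instruments;
observed effects add independent noise in the two samples
(`seExposure = 0.003`, `seOutcome = 0.02` by default) and p-values are exact
functions of the z-scores (floored at `1e-300` for representability).

Two deliberate choices shape the defaults:

* **Exposure-side precision.** With `seExposure = 0.003` — the precision of
  per-allele estimates in modern million-scale anthropometric GWAS — the
  instruments span $F \approx 40$–1100. Beyond instrument strength per se,
  what matters for MR-Egger is the *spread* of $\gamma_j$ relative to its
  measurement error: the regression-dilution factor is
  $\mathrm{var}(\gamma)/(\mathrm{var}(\gamma)+\sigma_x^2)$ (the
  $I^2_{GX}$ statistic). The defaults give $I^2_{GX} \approx 0.98$, so the
  Egger slope is attenuated by under 2%; had the effect spread been
  compressed (e.g. all $F$ squeezed into a narrow band), Egger would be
  biased toward the null by 30%+ no matter how large each individual $F$ is.
* **Summary-scale generation.** No individual-level genotypes are simulated;
  binary outcomes are generated directly on the log-odds scale. This
  reproduces exactly the two-sample summary setting the estimators see, at
  negligible cost, but it cannot exhibit finite-sample logistic
  non-collapsibility, winner's curse from instrument discovery in the same
  sample, sample overlap, or population stratification. Passing tests
  therefore validate the estimators *given* the standard summary-data model,
  not robustness to those upstream artifacts. LD, when requested, is an
  idealized block structure (constant within-block r²) meant for exercising
  the clumping logic, not for emulating real haplotype structure.

`injectOutliers` shifts selected outcome effects by a multiple of their
standard error (random or fixed sign) and `simulateMediation` adds a
heritable covariate: a fraction of instruments also affects the covariate
(effect correlated with instrument strength, as for genetically correlated
traits), and the covariate affects the outcome, so univariable MR is
confounded while multivariable MR adjusting for the covariate is not.

## The validation studies

The exported studies fix the designs used by the test suite and
`scripts/acceptance.R`:

* `calibrationStudy` — 1000 null datasets, $J=100$: type-I error of the IVW
  and Egger-intercept tests at 0.05, and a Kolmogorov–Smirnov uniformity
  check of the Q p-values. Note the multiplicative floor makes the IVW test
  conservative by construction: its exact size is
  $E[2\Phi(-1.96\sqrt{\max(1, Q/(J-1))})] \approx 0.045$, not 0.050, so
  empirical values cluster slightly below the nominal level.
* `recoveryStudy` — $\theta = 0.3$, $J = 150$, 500 replicates, with
  `seOutcome = 0.003` (a large continuous-outcome GWAS). The outcome
  precision matters for the weighted median: under one-sided invalid
  instruments its finite-sample bias is roughly $0.57\times$ the typical
  ratio standard error (the shift of the mixture's weighted 0.5-quantile),
  so the scenario's precision was set from that closed-form consideration,
  not by trial. Scenarios: clean (IVW mean), directional pleiotropy with
  InSIDE ($\mu_\alpha = 0.05$: Egger consistent, IVW biased by about
  $\mu_\alpha E_w[\gamma]/E_w[\gamma^2]$), and 30% invalid with large
  offsets (weighted median consistent).
* `pressoStudy` — 10% of instruments shifted by 10 se *in the same
  direction* (a shared pleiotropic pathway — the configuration the outlier
  and distortion machinery exists to correct; symmetric shifts cancel in
  the slope and constitute the distortion test's null), $J = 100$, 200
  replicates, 5000 simulations each: global-test power, pooled outlier
  recall and precision, and how often outlier removal moves the estimate
  toward the truth.
* `mediationStudy` — null direct effect with covariate mediation, 200
  replicates: the univariable IVW false-positive rate against the
  multivariable IVW type-I error.

Study sizes were chosen so the full battery runs in about a minute on one
CPU while leaving Monte-Carlo noise well inside the margins being tested.

## Numerical and policy choices

* **Duplicate variants** in an input table keep the smallest p-value
  (deterministic, logged); rows failing validation are dropped and counted.
* **Clumping ties** in p are broken by lexicographic variant id, making the
  result independent of input order; candidates without coordinates are
  excluded and counted; an r² missing for a within-window pair counts as 0
  (with a single summary warning when an LD table was supplied).
* **Missing variants** in the outcome are dropped with reason
  `dropped_missing`; no proxy-variant search is attempted.
* **Multivariable instrument assembly**: the union of genome-wide-significant
  variants across the exposure and covariate datasets is clumped jointly,
  ranked by each variant's minimum p-value across those datasets — which is
  why multivariable rows legitimately carry larger nSNP than univariable
  ones built from the exposure alone.
* **Instrument strength** uses the marginal chi-square form
  $F_j = (\hat\gamma_j/\sigma_{xj})^2$.
* **Degenerate inputs** fail loudly: $\hat\gamma_j = 0$ Wald ratios, fewer
  records than a method needs, collinear exposures, all instruments flagged
  as outliers. When MR-PRESSO flags nothing, the corrected estimate equals
  the full-set IVW and the result carries the explicit status
  `"no outliers detected"` (reports show `NA` with that note rather than a
  silent duplicate row).
* **Pipeline isolation**: exposure–outcome pairs run independently; one
  pair's failure is recorded in the bundle and the run continues.
* **Determinism**: every stochastic step (bootstrap, PRESSO simulations,
  distortion draws, generators) takes a seed derived from one analysis seed;
  reruns are bit-identical.

## Known limitations

No proxy-SNP lookup or genome-build liftover; r² must be supplied, not
computed from genotypes; no Steiger directionality filtering, mode-based
estimators, or Rücker model selection; figure rendering is limited to
scatter-data and fitted-line exports. The generator's idealizations are
listed above — conclusions about real data should lean on the sensitivity
battery (Egger intercept, weighted median, PRESSO, leave-one-out) exactly
because the clean summary-data model may not hold.
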