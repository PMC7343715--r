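# Report writing: delimited tables shaped like the conventional two-sample
# MR reporting (per-pair diagnostics row; five method rows per pair with
# OR (95% CI) formatting), plus scatter-data exports for per-pair plots, a
# machine-readable JSON summary, and the run log.

.safe_name <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

.fmt_or <- function(or, lo, hi) {
  ifelse(is.finite(or), sprintf("%.3f(%.3f,%.3f)", or, lo, hi), "NA")
}

.estimate_row <- function(e, note = "") {
  data.frame(exposure = e@exposure, outcome = e@outcome, method = e@method,
             nsnp = e@nsnp, beta = e@beta, se = e@se, ci_low = e@ciLow,
             ci_high = e@ciHigh, pvalue = e@pvalue, or = e@or,
             or_low = e@orLow, or_high = e@orHigh,
             or_95ci = .fmt_or(e@or, e@orLow, e@orHigh),
             note = note, stringsAsFactors = FALSE)
}

.empty_df <- function(cols) {
  df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                      cols))
  df
}

#' Write report tables for a ResultBundle
#'
#' Writes into `outdir`:
#' \describe{
#'   \item{`estimates.tsv`}{one row per pair and method (IVW,
#'     PRESSO-corrected, multivariable IVW when configured, weighted median,
#'     MR-Egger) with beta-scale and exponentiated-scale columns and an
#'     `or_95ci` string column formatted `"2.741(2.421,3.104)"`-style. A
#'     PRESSO-corrected row where no outliers were detected carries `NA`
#'     estimates and an explanatory note.}
#'   \item{`diagnostics.tsv`}{one row per pair: Q, Q df, Q p, PRESSO RSSobs
#'     and global p, Egger intercept with CI and p, outlier count,
#'     distortion p, status.}
#'   \item{`leave_one_out.tsv`}{long-format leave-one-out estimates for
#'     forest-style plots.}
#'   \item{`scatter_<pair>.tsv` and `fitted_lines.tsv`}{per-variant effects
#'     with ses, and the fitted IVW/Egger/weighted-median lines.}
#'   \item{`summary.json`, `run.log`}{machine-readable summary and log.}
#' }
#' An empty bundle produces header-only tables with a warning.
#'
#' @param bundle a [ResultBundle-class].
#' @param outdir output directory (created if needed); defaults to the
#'   config's `outdir` recorded in the bundle.
#' @return invisibly, the paths written.
#' @export
writeReport <- function(bundle, outdir = "mr-results") {
  stopifnot(is(bundle, "ResultBundle"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  paths <- character(0)

  ok_pairs <- Filter(function(p) is.null(p$error), bundle@pairs)
  if (!length(ok_pairs))
    warning("no successful pairs; writing header-only tables")

  est_rows <- list()
  diag_rows <- list()
  loo_rows <- list()
  line_rows <- list()
  for (p in ok_pairs) {
    for (e in p$estimates) {
      note <- if (e@method == "PRESSO-corrected" &&
                  p$presso@status == "no outliers detected")
        "no outliers detected" else ""
      row <- .estimate_row(e, note)
      if (nzchar(note)) {
        row[c("beta", "se", "ci_low", "ci_high", "pvalue", "or", "or_low",
              "or_high")] <- NA_real_
        row$or_95ci <- "NA"
      }
      est_rows[[length(est_rows) + 1L]] <- row
    }
    q <- p$heterogeneity
    eg <- p$estimates$`MR-Egger`
    diag_rows[[length(diag_rows) + 1L]] <- data.frame(
      exposure = p$exposure, outcome = p$outcome,
      Q = q@Q, Q_df = q@df, Q_p = q@pvalue,
      rss_obs = p$presso@rssObs, global_p = p$presso@globalP,
      egger_intercept = eg@intercept,
      intercept_ci_low = eg@interceptCiLow,
      intercept_ci_high = eg@interceptCiHigh,
      intercept_p = eg@pIntercept,
      n_outliers = length(p$presso@outlierIds),
      distortion_p = p$presso@distortionP,
      presso_status = p$presso@status, stringsAsFactors = FALSE)
    le <- p$loo@estimates
    loo_rows[[length(loo_rows) + 1L]] <- data.frame(
      exposure = p$exposure, outcome = p$outcome, le,
      overall_beta = p$loo@overall@beta, stringsAsFactors = FALSE)
    for (m in c("IVW", "WeightedMedian", "MR-Egger")) {
      e <- p$estimates[[m]]
      if (is.null(e)) next
      line_rows[[length(line_rows) + 1L]] <- data.frame(
        exposure = p$exposure, outcome = p$outcome, method = m,
        intercept = if (is.finite(e@intercept)) e@intercept else 0,
        slope = e@beta, stringsAsFactors = FALSE)
    }
    sd <- harmonizedData(p$harmonized)
    scatter <- sd[, c("variant_id", "gamma", "se_gamma", "Gamma",
                      "se_Gamma")]
    sp <- file.path(outdir, sprintf("scatter_%s_%s.tsv",
                                    .safe_name(p$exposure),
                                    .safe_name(p$outcome)))
    data.table::fwrite(scatter, sp, sep = "\t", quote = FALSE)
    paths <- c(paths, sp)
  }

  write_tbl <- function(rows, file, cols) {
    df <- if (length(rows)) do.call(rbind, rows) else .empty_df(cols)
    fp <- file.path(outdir, file)
    data.table::fwrite(df, fp, sep = "\t", na = "NA", quote = FALSE)
    fp
  }
  paths <- c(paths,
    write_tbl(est_rows, "estimates.tsv",
              c("exposure", "outcome", "method", "nsnp", "beta", "se",
                "ci_low", "ci_high", "pvalue", "or", "or_low", "or_high",
                "or_95ci", "note")),
    write_tbl(diag_rows, "diagnostics.tsv",
              c("exposure", "outcome", "Q", "Q_df", "Q_p", "rss_obs",
                "global_p", "egger_intercept", "intercept_ci_low",
                "intercept_ci_high", "intercept_p", "n_outliers",
                "distortion_p", "presso_status")),
    write_tbl(loo_rows, "leave_one_out.tsv",
              c("exposure", "outcome", "excluded", "beta", "se", "ciLow",
                "ciHigh", "pvalue", "overall_beta")),
    write_tbl(line_rows, "fitted_lines.tsv",
              c("exposure", "outcome", "method", "intercept", "slope")))

  summarize_pair <- function(p) {
    if (!is.null(p$error)) return(list(error = p$error))
    list(ivw_beta = p$estimates$IVW@beta,
         ivw_p = p$estimates$IVW@pvalue,
         n_instruments = length(p$instruments@variantIds),
         min_F = min(p$instruments@fstat),
         mean_F = mean(p$instruments@fstat),
         max_F = max(p$instruments@fstat),
         q_p = p$heterogeneity@pvalue,
         presso_global_p = p$presso@globalP,
         n_outliers = length(p$presso@outlierIds),
         loo_max_abs_shift = p$loo@maxAbsShift)
  }
  jp <- file.path(outdir, "summary.json")
  jsonlite::write_json(
    list(settings = bundle@settings,
         pairs = lapply(bundle@pairs, summarize_pair)),
    jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  lp <- file.path(outdir, "run.log")
  writeLines(bundle@log, lp)
  invisible(c(paths, jp, lp))
}
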