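#' Construct a GwasSummary from a data.frame
#'
#' Rows violating the per-variant invariants (alleles in A/C/G/T and
#' distinct, `se > 0`, `eaf` in \[0, 1\] or missing, `pvalue` in (0, 1\]) are
#' dropped with a logged count. Duplicate `variant_id`s are resolved by
#' keeping the row with the smallest p-value.
#'
#' @param trait trait name.
#' @param unit unit of the per-allele effect (e.g. `"SD"`, `"log odds"`).
#' @param data data.frame with (at least) the columns listed under
#'   [GwasSummary-class].
#' @param dropLog named list of counts carried over from reading.
#' @return a [GwasSummary-class] object.
#' @export
gwasSummary <- function(trait, unit, data, dropLog = list()) {
  data <- as.data.frame(data)
  miss <- setdiff(.GWAS_COLS, names(data))
  if ("n" %in% miss) { data$n <- NA_real_; miss <- setdiff(miss, "n") }
  if ("eaf" %in% miss) { data$eaf <- NA_real_; miss <- setdiff(miss, "eaf") }
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  data <- data[, .GWAS_COLS]
  data$variant_id <- as.character(data$variant_id)
  data$chrom <- as.character(data$chrom)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n"))
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))

  n0 <- nrow(data)
  ok <- !is.na(data$variant_id) & nzchar(data$variant_id) &
    data$effect_allele %in% .ALLELES & data$other_allele %in% .ALLELES &
    data$effect_allele != data$other_allele &
    is.finite(data$beta) & is.finite(data$se) & data$se > 0 &
    is.finite(data$pvalue) & data$pvalue > 0 & data$pvalue <= 1 &
    (is.na(data$eaf) | (data$eaf >= 0 & data$eaf <= 1))
  dropped_invalid <- sum(!ok)
  data <- data[ok, , drop = FALSE]

  dup <- 0L
  if (anyDuplicated(data$variant_id)) {
    ord <- order(data$pvalue, data$variant_id)
    data <- data[ord, , drop = FALSE]
    dupes <- duplicated(data$variant_id)
    dup <- sum(dupes)
    data <- data[!dupes, , drop = FALSE]
  }
  rownames(data) <- NULL
  if (!nrow(data))
    stop("no valid rows for trait '", trait, "' (", n0, " read, ",
         dropped_invalid, " failed validation)")

  log <- utils::modifyList(list(read = n0), dropLog)
  log$dropped_invalid <- dropped_invalid + (log$dropped_invalid %||% 0L)
  log$dropped_duplicate <- dup + (log$dropped_duplicate %||% 0L)
  new("GwasSummary", trait = trait, unit = unit, data = data, dropLog = log)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text file (tab, comma or whitespace separated;
#' optionally gzip-compressed), maps its columns to the semantic fields and
#' validates the rows. Invalid rows are dropped with a logged count;
#' duplicate variant ids are resolved by keeping the smallest p-value.
#'
#' @param path file path.
#' @param columnMap named character vector mapping semantic field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`) to column names in the file. Fields absent
#'   from the map are assumed to use the semantic name itself; `eaf` and `n`
#'   are optional.
#' @param trait trait name; defaults to the file name.
#' @param unit unit label of the effect sizes (Table-1 style, e.g. `"SD"`,
#'   `"log odds"`, `"mmol/L"`).
#' @return a [GwasSummary-class].
#' @export
readSummaryStats <- function(path, columnMap = NULL, trait = NULL,
                             unit = "SD") {
  if (!file.exists(path)) stop("cannot read summary-statistics file: ", path)
  trait <- trait %||% sub("\\.(txt|tsv|csv|gz)+$", "", basename(path))
  dt <- tryCatch({
    if (grepl("\\.gz$", path)) {
      con <- gzfile(path, "r")
      on.exit(close(con), add = TRUE)
      data.table::fread(text = readLines(con), header = TRUE,
                        data.table = FALSE, showProgress = FALSE)
    } else {
      data.table::fread(path, header = TRUE, data.table = FALSE,
                        showProgress = FALSE)
    }
  }, error = function(e) stop("unreadable file '", path, "': ",
                              conditionMessage(e)))
  if (!nrow(dt)) stop("empty summary-statistics file: ", path)

  map <- c(variant_id = "variant_id", chrom = "chrom", pos = "pos",
           effect_allele = "effect_allele", other_allele = "other_allele",
           eaf = "eaf", beta = "beta", se = "se", pvalue = "pvalue", n = "n")
  if (!is.null(columnMap)) map[names(columnMap)] <- columnMap

  required <- setdiff(.GWAS_COLS, c("eaf", "n"))
  miss <- required[!map[required] %in% names(dt)]
  if (length(miss))
    stop("mapped columns not present in ", path, ": ",
         paste(map[miss], collapse = ", "))

  out <- data.frame(row.names = seq_len(nrow(dt)))
  for (f in .GWAS_COLS) {
    out[[f]] <- if (map[[f]] %in% names(dt)) dt[[map[[f]]]] else NA
  }
  gwasSummary(trait = trait, unit = unit, data = out)
}

#' Write a GwasSummary as tab-delimited text
#'
#' @param x a [GwasSummary-class].
#' @param path output path (`.gz` supported).
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(x, path) {
  stopifnot(is(x, "GwasSummary"))
  data.table::fwrite(x@data, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Harmonize exposure and outcome effects onto a shared effect allele
#'
#' For each requested variant present in both datasets the outcome record is
#' aligned to the exposure's effect allele: matching alleles are kept,
#' swapped alleles are flipped (outcome effect negated, outcome frequency
#' reflected). Palindromic variants (A/T or C/G) cannot be resolved from
#' allele labels, so they are aligned by effect-allele-frequency concordance
#' when both frequencies are available and outside the ambiguity window, and
#' dropped otherwise. Variants with irreconcilable alleles or absent from
#' either dataset are dropped with the reason recorded; no proxy search is
#' attempted.
#'
#' @param exposure,outcome [GwasSummary-class] objects.
#' @param variantIds variants to harmonize; defaults to all exposure ids.
#' @param eafWindow frequency window within which a palindromic variant is
#'   considered ambiguous (default `c(0.42, 0.58)`).
#' @return a [HarmonizedPair-class] with one row per requested variant.
#' @export
harmonizePair <- function(exposure, outcome, variantIds = NULL,
                          eafWindow = c(0.42, 0.58)) {
  stopifnot(is(exposure, "GwasSummary"), is(outcome, "GwasSummary"))
  ed <- exposure@data
  od <- outcome@data
  variantIds <- unique(as.character(variantIds %||% ed$variant_id))
  if (!length(variantIds)) stop("variantIds must be nonempty")

  ei <- match(variantIds, ed$variant_id)
  oi <- match(variantIds, od$variant_id)
  n <- length(variantIds)

  action <- rep("dropped_missing", n)
  gamma <- se_gamma <- Gamma <- se_Gamma <- rep(NA_real_, n)
  eeaf <- oeaf <- rep(NA_real_, n)
  ea <- oa <- rep(NA_character_, n)

  both <- !is.na(ei) & !is.na(oi)
  if (any(both)) {
    e <- ed[ei[both], ]
    o <- od[oi[both], ]
    pal <- .is_palindromic(e$effect_allele, e$other_allele)
    same <- o$effect_allele == e$effect_allele &
            o$other_allele == e$other_allele
    swap <- o$effect_allele == e$other_allele &
            o$other_allele == e$effect_allele

    act <- rep("dropped_incompatible", nrow(e))
    flipG <- rep(FALSE, nrow(e))

    # Non-palindromic: allele labels decide (forward strand assumed).
    act[!pal & same] <- "kept"
    act[!pal & swap] <- "flipped"
    flipG[!pal & swap] <- TRUE

    # Palindromic: labels are strand-ambiguous; frequencies decide.
    pal_set <- pal & (same | swap)
    if (any(pal_set)) {
      ef <- e$eaf[pal_set]
      of <- o$eaf[pal_set]
      ambiguous <- is.na(ef) | is.na(of) |
        (ef >= eafWindow[1] & ef <= eafWindow[2]) |
        (of >= eafWindow[1] & of <= eafWindow[2])
      concord <- (ef < 0.5) == (of < 0.5)
      a <- ifelse(ambiguous, "dropped_palindromic",
                  ifelse(concord, "kept", "flipped"))
      act[pal_set] <- a
      flipG[pal_set] <- !ambiguous & !concord
    }

    keep <- act %in% c("kept", "flipped")
    idx <- which(both)
    action[idx] <- act
    ea[idx] <- e$effect_allele
    oa[idx] <- e$other_allele
    gamma[idx[keep]] <- e$beta[keep]
    se_gamma[idx[keep]] <- e$se[keep]
    Gamma[idx[keep]] <- ifelse(flipG[keep], -o$beta[keep], o$beta[keep])
    se_Gamma[idx[keep]] <- o$se[keep]
    eeaf[idx[keep]] <- e$eaf[keep]
    oeaf[idx[keep]] <- ifelse(flipG[keep] & !is.na(o$eaf[keep]),
                              1 - o$eaf[keep], o$eaf[keep])
  }

  d <- data.frame(variant_id = variantIds, effect_allele = ea,
                  other_allele = oa, gamma = gamma, se_gamma = se_gamma,
                  Gamma = Gamma, se_Gamma = se_Gamma, exposure_eaf = eeaf,
                  outcome_eaf = oeaf, action = action,
                  stringsAsFactors = FALSE)
  new("HarmonizedPair", exposure = exposure@trait, outcome = outcome@trait,
      exposureUnit = exposure@unit, outcomeUnit = outcome@unit,
      eafWindow = eafWindow, data = d)
}

#' Harmonize several exposures and an outcome onto shared alleles
#'
#' Every dataset is aligned to the first exposure's effect alleles; only
#' variants harmonizable (kept or flipped) across *all* datasets are
#' retained, so a variant allele-incompatible in a single covariate dataset
#' is excluded even if it harmonizes pairwise.
#'
#' @param exposures list of two or more [GwasSummary-class] objects (main
#'   exposure first, then covariates).
#' @param outcome a [GwasSummary-class].
#' @param variantIds variants to harmonize; defaults to all ids of the first
#'   exposure.
#' @param eafWindow see [harmonizePair()].
#' @return a [HarmonizedMulti-class] with one `gamma_<trait>` /
#'   `se_gamma_<trait>` pair per exposure plus `Gamma` / `se_Gamma`.
#' @export
harmonizeMulti <- function(exposures, outcome, variantIds = NULL,
                           eafWindow = c(0.42, 0.58)) {
  if (!is.list(exposures) || length(exposures) < 2L)
    stop("harmonizeMulti requires at least 2 exposure datasets")
  stopifnot(all(vapply(exposures, is, logical(1), "GwasSummary")),
            is(outcome, "GwasSummary"))
  ref <- exposures[[1]]
  variantIds <- unique(as.character(variantIds %||% ref@data$variant_id))

  pairs <- lapply(exposures[-1], function(ds)
    harmonizePair(ref, ds, variantIds, eafWindow))
  outPair <- harmonizePair(ref, outcome, variantIds, eafWindow)

  keep_ids <- outPair@data$variant_id[
    outPair@data$action %in% c("kept", "flipped")]
  for (hp in pairs) {
    keep_ids <- intersect(keep_ids, hp@data$variant_id[
      hp@data$action %in% c("kept", "flipped")])
  }

  traits <- vapply(exposures, function(x) x@trait, character(1))
  if (anyDuplicated(traits))
    traits <- make.unique(traits, sep = "_")
  if (length(keep_ids) < length(exposures) + 1L)
    stop("underdetermined system: ", length(keep_ids),
         " harmonizable variants for ", length(exposures), " exposures")

  rd <- outPair@data[match(keep_ids, outPair@data$variant_id), ]
  d <- data.frame(variant_id = keep_ids,
                  effect_allele = rd$effect_allele,
                  other_allele = rd$other_allele,
                  stringsAsFactors = FALSE)
  d[[paste0("gamma_", traits[1])]] <- rd$gamma
  d[[paste0("se_gamma_", traits[1])]] <- rd$se_gamma
  for (k in seq_along(pairs)) {
    pd <- pairs[[k]]@data[match(keep_ids, pairs[[k]]@data$variant_id), ]
    # In the aligning pair the k-th exposure sits in the outcome position.
    d[[paste0("gamma_", traits[k + 1])]] <- pd$Gamma
    d[[paste0("se_gamma_", traits[k + 1])]] <- pd$se_Gamma
  }
  d$Gamma <- rd$Gamma
  d$se_Gamma <- rd$se_Gamma
  rownames(d) <- NULL
  new("HarmonizedMulti", exposures = traits, outcome = outcome@trait,
      outcomeUnit = outcome@unit, data = d)
}

#' Write a harmonized table as tab-delimited text
#'
#' Fixed header: `variant_id`, `effect_allele`, `other_allele`, `gamma`,
#' `se_gamma`, `Gamma`, `se_Gamma`, `action`.
#'
#' @param x a [HarmonizedPair-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHarmonized <- function(x, path) {
  stopifnot(is(x, "HarmonizedPair"))
  cols <- c("variant_id", "effect_allele", "other_allele", "gamma",
            "se_gamma", "Gamma", "se_Gamma", "action")
  data.table::fwrite(x@data[, cols], path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

## Accessors ------------------------------------------------------------

#' Accessors for mrkit objects
#'
#' @param x an mrkit S4 object.
#' @param retained for `harmonizedData`, return only kept/flipped records.
#' @name accessors
NULL

#' @rdname accessors
setMethod("traitName", "GwasSummary", function(x) x@trait)
#' @rdname accessors
setMethod("traitUnit", "GwasSummary", function(x) x@unit)
#' @rdname accessors
setMethod("variantData", "GwasSummary", function(x) x@data)
#' @rdname accessors
setMethod("nVariants", "GwasSummary", function(x) nrow(x@data))
#' @rdname accessors
setMethod("dropLog", "GwasSummary", function(x) x@dropLog)

#' @rdname accessors
setMethod("harmonizedData", "HarmonizedPair", function(x, retained = TRUE) {
  if (retained) x@data[x@data$action %in% c("kept", "flipped"), , drop = FALSE]
  else x@data
})
#' @rdname accessors
setMethod("harmonizedData", "HarmonizedMulti",
          function(x, retained = TRUE) x@data)

#' @rdname accessors
setMethod("actionCounts", "HarmonizedPair", function(x) {
  counts <- table(factor(x@data$action, levels = .ACTIONS))
  stats::setNames(as.integer(counts), names(counts))
})

setMethod("show", "GwasSummary", function(object) {
  cat("GwasSummary:", object@trait, "(", object@unit, ")\n")
  cat("  ", nrow(object@data), "variants\n")
  dl <- object@dropLog
  if (length(dl))
    cat("  drop log:", paste(names(dl), unlist(dl), sep = "=",
                             collapse = ", "), "\n")
})

setMethod("show", "HarmonizedPair", function(object) {
  cat("HarmonizedPair:", object@exposure, "->", object@outcome, "\n")
  ac <- actionCounts(object)
  cat("  ", paste(names(ac), ac, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "HarmonizedMulti", function(object) {
  cat("HarmonizedMulti:", paste(object@exposures, collapse = " + "),
      "->", object@outcome, "\n")
  cat("  ", nrow(object@data), "variants retained across all datasets\n")
})
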