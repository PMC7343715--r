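#' Select genome-wide-significant variants
#'
#' Returns the ids of variants strictly below the significance threshold
#' (the conventional genome-wide threshold 5.0e-8 by default; a variant with
#' p exactly at the threshold is excluded).
#'
#' @param exposure a [GwasSummary-class].
#' @param pThreshold significance threshold in (0, 1).
#' @return character vector of variant ids.
#' @export
selectSignificant <- function(exposure, pThreshold = 5e-8) {
  stopifnot(is(exposure, "GwasSummary"))
  if (!is.finite(pThreshold) || pThreshold <= 0 || pThreshold >= 1)
    stop("pThreshold must lie in (0, 1)")
  ids <- exposure@data$variant_id[exposure@data$pvalue < pThreshold]
  if (!length(ids))
    stop("no instruments: no variant reaches p < ", format(pThreshold),
         " for trait '", exposure@trait, "'")
  ids
}

#' Read pairwise LD information
#'
#' Three-column delimited text: `id_a`, `id_b`, `r2`. The relation is
#' symmetric; each unordered pair needs to appear once.
#'
#' @param path file path.
#' @return data.frame with columns `id_a`, `id_b`, `r2`.
#' @export
readLdInfo <- function(path) {
  ld <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          showProgress = FALSE)
  if (ncol(ld) < 3) stop("LD file must have columns id_a, id_b, r2")
  names(ld)[1:3] <- c("id_a", "id_b", "r2")
  if (any(ld$r2 < 0 | ld$r2 > 1, na.rm = TRUE))
    stop("r2 values must lie in [0, 1]")
  ld[, 1:3]
}

.ld_lookup <- function(ld) {
  if (is.null(ld) || !nrow(ld)) return(NULL)
  key <- paste(pmin(ld$id_a, ld$id_b), pmax(ld$id_a, ld$id_b), sep = "\r")
  stats::setNames(ld$r2, key)
}

#' Greedy LD clumping
#'
#' Candidates are ranked by ascending p-value (ties broken by variant id);
#' the top remaining variant becomes an index variant and removes every
#' other candidate on the same chromosome within `windowKb` of it whose
#' squared correlation with it is at least `r2Threshold`. The defaults
#' (`r2 = 0.001`, window 10,000 kb) follow standard instrument-pruning
#' practice.
#'
#' A pair absent from `ld` is treated as r2 = 0; if `ld` was supplied but
#' within-window pairs are missing from it, a single warning reports how
#' many lookups defaulted to 0. Candidates without coordinates are excluded
#' and counted in the `"excluded_missing_pos"` attribute of the result.
#'
#' @param candidates character vector of variant ids.
#' @param exposure the [GwasSummary-class] carrying p-values and positions.
#' @param ld optional data.frame (`id_a`, `id_b`, `r2`) as read by
#'   [readLdInfo()]; `NULL` means no LD information (distance alone never
#'   removes a variant, since r2 defaults to 0).
#' @param r2Threshold squared-correlation threshold (default 0.001).
#' @param windowKb clumping distance in kb (default 10,000).
#' @return character vector of index variant ids in selection order, with
#'   attribute `excluded_missing_pos`.
#' @export
ldClump <- function(candidates, exposure, ld = NULL, r2Threshold = 0.001,
                    windowKb = 10000) {
  stopifnot(is(exposure, "GwasSummary"))
  candidates <- unique(as.character(candidates))
  d <- exposure@data[match(candidates, exposure@data$variant_id), ]
  present <- !is.na(d$variant_id)
  if (any(!present))
    stop("candidates absent from exposure dataset: ",
         paste(head(candidates[!present], 5), collapse = ", "))

  has_pos <- !is.na(d$chrom) & nzchar(d$chrom) & is.finite(d$pos)
  n_missing_pos <- sum(!has_pos)
  d <- d[has_pos, , drop = FALSE]
  if (!nrow(d)) {
    out <- character(0)
    attr(out, "excluded_missing_pos") <- n_missing_pos
    return(out)
  }

  ord <- order(d$pvalue, d$variant_id)
  d <- d[ord, , drop = FALSE]
  lut <- .ld_lookup(ld)
  window_bp <- windowKb * 1000

  alive <- rep(TRUE, nrow(d))
  keep <- character(0)
  n_missing_r2 <- 0L
  for (i in seq_len(nrow(d))) {
    if (!alive[i]) next
    keep <- c(keep, d$variant_id[i])
    alive[i] <- FALSE
    cand <- which(alive & d$chrom == d$chrom[i] &
                  abs(d$pos - d$pos[i]) <= window_bp)
    if (!length(cand)) next
    if (is.null(lut)) {
      r2 <- rep(0, length(cand))
    } else {
      key <- paste(pmin(d$variant_id[i], d$variant_id[cand]),
                   pmax(d$variant_id[i], d$variant_id[cand]), sep = "\r")
      r2 <- unname(lut[key])
      n_missing_r2 <- n_missing_r2 + sum(is.na(r2))
      r2[is.na(r2)] <- 0
    }
    alive[cand[r2 >= r2Threshold]] <- FALSE
  }
  if (!is.null(lut) && n_missing_r2 > 0)
    warning(n_missing_r2, " within-window pair(s) missing from the LD ",
            "table; r2 treated as 0")
  attr(keep, "excluded_missing_pos") <- n_missing_pos
  keep
}

#' Instrument strength (per-variant F statistics)
#'
#' Per-variant `F = (beta / se)^2`, the square of the marginal z-score.
#' Instruments with `F <= weakThreshold` are flagged as weak but not removed
#' (the conventional adequacy threshold is F > 10).
#'
#' @param instruments character vector of instrument ids.
#' @param exposure the [GwasSummary-class] the instruments were selected from.
#' @param weakThreshold flagging threshold (default 10).
#' @param selectionLog optional named list of counts at earlier filter stages,
#'   stored alongside.
#' @return an [InstrumentSet-class].
#' @export
instrumentStrength <- function(instruments, exposure, weakThreshold = 10,
                               selectionLog = list()) {
  stopifnot(is(exposure, "GwasSummary"))
  instruments <- as.character(instruments)
  if (!length(instruments)) stop("instruments must be nonempty")
  idx <- match(instruments, exposure@data$variant_id)
  if (anyNA(idx))
    stop("instruments absent from exposure dataset: ",
         paste(head(instruments[is.na(idx)], 5), collapse = ", "))
  f <- (exposure@data$beta[idx] / exposure@data$se[idx])^2
  names(f) <- instruments
  weak <- instruments[f <= weakThreshold]
  log <- utils::modifyList(list(n_instruments = length(instruments),
                                n_weak = length(weak)), selectionLog)
  new("InstrumentSet", variantIds = instruments, fstat = f,
      weakThreshold = weakThreshold, weakIds = weak, selectionLog = log)
}

#' @rdname accessors
setMethod("instrumentIds", "InstrumentSet", function(x) x@variantIds)
#' @rdname accessors
setMethod("fStatistics", "InstrumentSet", function(x) x@fstat)

#' Write an InstrumentSet as delimited text
#'
#' Per-variant F table followed by a one-line min/mean/max summary (as a
#' comment line at the top).
#'
#' @param x an [InstrumentSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeInstrumentSet <- function(x, path) {
  stopifnot(is(x, "InstrumentSet"))
  hdr <- sprintf("# n=%d min_F=%.3f mean_F=%.3f max_F=%.3f n_weak=%d",
                 length(x@variantIds), min(x@fstat), mean(x@fstat),
                 max(x@fstat), length(x@weakIds))
  writeLines(c(hdr, "variant_id\tF\tweak"), path)
  data.table::fwrite(
    data.frame(variant_id = x@variantIds, F = x@fstat,
               weak = x@variantIds %in% x@weakIds),
    path, sep = "\t", quote = FALSE, append = TRUE, col.names = FALSE)
  invisible(path)
}

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet:", length(object@variantIds), "instruments\n")
  cat(sprintf("  F: min %.3f, mean %.3f, max %.3f; %d flagged weak (F <= %g)\n",
              min(object@fstat), mean(object@fstat), max(object@fstat),
              length(object@weakIds), object@weakThreshold))
})
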