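test_that("summary tables are read, validated and deduplicated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- make_variant_df(c("rs1", "rs2"), c("A", "C"), c("G", "T"),
                        beta = c(0.1, -0.2), se = c(0.01, 0.02),
                        eaf = c(0.3, 0.4), n = 1000)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  ds <- readSummaryStats(path, trait = "toy", unit = "SD")
  expect_s4_class(ds, "GwasSummary")
  expect_equal(nVariants(ds), 2L)
  expect_equal(traitUnit(ds), "SD")

  # an se = 0 row is dropped and counted
  df_bad <- rbind(df, make_variant_df("rs3", "A", "G", beta = 0.1, se = 0,
                                      pvalue = 0.5))
  write.table(df_bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  ds2 <- readSummaryStats(path, trait = "toy")
  expect_equal(nVariants(ds2), 2L)
  expect_equal(dropLog(ds2)$dropped_invalid, 1L)

  # duplicates resolved by smallest p-value
  df_dup <- rbind(df, make_variant_df("rs1", "A", "G", beta = 0.5,
                                      se = 0.01))
  write.table(df_dup, path, sep = "\t", row.names = FALSE, quote = FALSE)
  ds3 <- readSummaryStats(path, trait = "toy")
  expect_equal(nVariants(ds3), 2L)
  d1 <- variantData(ds3)
  expect_equal(d1$beta[d1$variant_id == "rs1"], 0.5) # |z|=50 beats |z|=10
  expect_equal(dropLog(ds3)$dropped_duplicate, 1L)

  # disease outcome on the log-odds scale keeps its unit label
  ds4 <- readSummaryStats(path, trait = "T2DM", unit = "log odds")
  expect_equal(traitUnit(ds4), "log odds")
})

test_that("column mapping and comma/gzip input are handled", {
  path <- withr::local_tempfile(fileext = ".csv.gz")
  df <- data.frame(SNP = c("rs1", "rs2"), CHR = "2", BP = c(100, 200),
                   A1 = c("A", "T"), A2 = c("G", "C"), FREQ = c(0.2, 0.7),
                   BETA = c(0.05, 0.07), SE = c(0.01, 0.01),
                   P = c(1e-8, 1e-12), N = 5e5)
  con <- gzfile(path, "w")
  write.csv(df, con, row.names = FALSE)
  close(con)
  ds <- readSummaryStats(path, columnMap = c(
    variant_id = "SNP", chrom = "CHR", pos = "BP", effect_allele = "A1",
    other_allele = "A2", eaf = "FREQ", beta = "BETA", se = "SE",
    pvalue = "P", n = "N"), trait = "mapped")
  expect_equal(nVariants(ds), 2L)
  expect_equal(variantData(ds)$pos, c(100, 200))
  expect_error(readSummaryStats(path, columnMap = c(beta = "nope")),
               "not present")
  expect_error(readSummaryStats("/does/not/exist.tsv"), "cannot read")
})

test_that("allele harmonization follows the label and frequency rules", {
  exposure <- make_gwas(c("rs_swap", "rs_pal_mid", "rs_pal_low", "rs_bad",
                          "rs_only_exp", "rs_keep"),
                        ea = c("A", "A", "A", "A", "A", "C"),
                        oa = c("G", "T", "T", "G", "G", "T"),
                        beta = c(0.10, 0.10, 0.10, 0.10, 0.10, 0.10),
                        se = 0.01,
                        eaf = c(0.3, 0.50, 0.11, 0.3, 0.3, 0.3),
                        trait = "exp")
  outcome <- make_gwas(c("rs_swap", "rs_pal_mid", "rs_pal_low", "rs_bad",
                         "rs_keep"),
                       ea = c("G", "A", "A", "C", "C"),
                       oa = c("A", "T", "T", "T", "T"),
                       beta = c(-0.05, 0.02, 0.03, 0.02, 0.04),
                       se = 0.01,
                       eaf = c(0.7, 0.50, 0.88, 0.3, 0.3),
                       trait = "out")
  hp <- harmonizePair(exposure, outcome)
  d <- harmonizedData(hp, retained = FALSE)
  act <- setNames(d$action, d$variant_id)

  # swapped labels: flipped, outcome beta negated
  expect_equal(act[["rs_swap"]], "flipped")
  expect_equal(d$Gamma[d$variant_id == "rs_swap"], 0.05)
  expect_equal(d$outcome_eaf[d$variant_id == "rs_swap"], 0.3)
  # palindromic with eaf in the ambiguity window: dropped
  expect_equal(act[["rs_pal_mid"]], "dropped_palindromic")
  # palindromic, frequencies discordant (0.11 vs 0.88): aligned by flipping
  expect_equal(act[["rs_pal_low"]], "flipped")
  expect_equal(d$Gamma[d$variant_id == "rs_pal_low"], -0.03)
  # irreconcilable alleles
  expect_equal(act[["rs_bad"]], "dropped_incompatible")
  # absent from outcome
  expect_equal(act[["rs_only_exp"]], "dropped_missing")
  # matching labels kept unchanged
  expect_equal(act[["rs_keep"]], "kept")
  expect_equal(d$Gamma[d$variant_id == "rs_keep"], 0.04)

  # counts reconcile with the request
  expect_equal(sum(actionCounts(hp)), 6L)
})

test_that("harmonization of a dataset against itself is the identity", {
  set.seed(7)
  sim <- simulateSummaryStats(simConfig(J = 40, propPalindromic = 0.2),
                              simTruth(theta = 0.2, seed = 99))
  hp <- harmonizePair(sim$exposure, sim$exposure)
  d <- harmonizedData(hp, retained = FALSE)
  pal <- mrkit:::.is_palindromic(variantData(sim$exposure)$effect_allele,
                                 variantData(sim$exposure)$other_allele)
  expect_true(all(d$action[!pal] == "kept"))
  keep <- d$action %in% c("kept", "flipped")
  expect_true(all(d$action[keep] == "kept"))
  expect_identical(d$Gamma[keep], d$gamma[keep])
})

test_that("consistent allele-label flips leave causal estimates unchanged", {
  set.seed(21)
  sim <- simulateSummaryStats(simConfig(J = 60),
                              simTruth(theta = 0.25, seed = 13))
  flip_labels <- function(ds, idx) {
    d <- variantData(ds)
    tmp <- d$effect_allele[idx]
    d$effect_allele[idx] <- d$other_allele[idx]
    d$other_allele[idx] <- tmp
    d$beta[idx] <- -d$beta[idx]
    d$eaf[idx] <- 1 - d$eaf[idx]
    gwasSummary(traitName(ds), traitUnit(ds), d)
  }
  idx <- sample(60, 25)
  hp1 <- harmonizePair(sim$exposure, sim$outcome)
  hp2 <- harmonizePair(flip_labels(sim$exposure, idx),
                       flip_labels(sim$outcome, idx))
  expect_equal(mrBeta(mrIVW(hp2)), mrBeta(mrIVW(hp1)), tolerance = 1e-12)
  expect_equal(mrBeta(mrEgger(hp2)), mrBeta(mrEgger(hp1)),
               tolerance = 1e-12)
  expect_equal(mrBeta(mrWeightedMedian(hp2, nBoot = 0)),
               mrBeta(mrWeightedMedian(hp1, nBoot = 0)), tolerance = 1e-12)

  # flipping only one study's labels is undone by harmonization itself
  hp3 <- harmonizePair(flip_labels(sim$exposure, seq_len(60)), sim$outcome)
  expect_true(all(harmonizedData(hp3, retained = FALSE)$action == "flipped"))
  expect_equal(mrBeta(mrIVW(hp3)), mrBeta(mrIVW(hp1)), tolerance = 1e-12)
})

test_that("multivariable harmonization keeps the all-dataset intersection", {
  ids <- paste0("rs", 1:10)
  e1 <- make_gwas(ids, ea = "A", oa = "G", beta = seq(0.05, 0.14, 0.01),
                  se = 0.01, eaf = 0.3, trait = "bmi")
  e2 <- make_gwas(ids, ea = "A", oa = "G", beta = rep(0.08, 10), se = 0.01,
                  eaf = 0.3, trait = "sbp")
  out <- make_gwas(ids, ea = "A", oa = "G", beta = rep(0.02, 10), se = 0.01,
                   eaf = 0.3, trait = "t2dm", unit = "log odds")
  mh <- harmonizeMulti(list(e1, e2), out)
  expect_s4_class(mh, "HarmonizedMulti")
  d <- harmonizedData(mh)
  expect_equal(nrow(d), 10L)
  expect_true(all(c("gamma_bmi", "se_gamma_bmi", "gamma_sbp",
                    "se_gamma_sbp", "Gamma", "se_Gamma") %in% names(d)))

  # a variant allele-incompatible in one covariate dataset is excluded even
  # though it harmonizes pairwise with the outcome
  d2 <- variantData(e2)
  d2$other_allele[d2$variant_id == "rs3"] <- "C"
  mh2 <- harmonizeMulti(list(e1, gwasSummary("sbp", "SD", d2)), out)
  expect_false("rs3" %in% harmonizedData(mh2)$variant_id)
  expect_equal(nrow(harmonizedData(mh2)), 9L)

  expect_error(harmonizeMulti(list(e1), out), "at least 2")
  # too few shared variants for the number of exposures
  expect_error(harmonizeMulti(list(e1, e2), out, variantIds = c("rs1", "rs2")),
               "underdetermined")
})

test_that("harmonized tables round-trip through the fixed-header export", {
  sim <- simulateSummaryStats(simConfig(J = 10),
                              simTruth(theta = 0.1, seed = 5))
  hp <- harmonizePair(sim$exposure, sim$outcome)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeHarmonized(hp, path)
  back <- read.delim(path)
  expect_identical(names(back),
                   c("variant_id", "effect_allele", "other_allele", "gamma",
                     "se_gamma", "Gamma", "se_Gamma", "action"))
  expect_equal(nrow(back), 10L)
})
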