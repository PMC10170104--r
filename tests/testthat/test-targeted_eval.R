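tryptophan_table <- function(extra = NULL) {
  feats <- rbind(data.frame(feature_id = "F01", mz = 205.0975, rt = 140,
                            annotation = NA_character_,
                            stringsAsFactors = FALSE), extra)
  areas <- matrix(1000, nrow(feats), 4)
  feature_table(areas, feats, make_samples(c(I = 2, III = 2)))
}

test_that("tryptophan matches its registry record within tolerance", {
  reg <- read_registry(moint_registry_path())
  mt <- match_compounds(tryptophan_table(), reg, mz_tol_ppm = 5,
                        rt_tol_s = 10)
  trp <- mt$matches[mt$matches$name == "Tryptophan", ]
  expect_equal(nrow(trp), 1)
  expect_equal(trp$feature_id, "F01")
  expect_equal(trp$mz_error_ppm, (205.0975 - 205.097) / 205.097 * 1e6,
               tolerance = 1e-9)    # ~2.4 ppm
  expect_equal(trp$rt_error_s, 1)
  # everything unmatched is reported with a reason
  reg_run <- reg[reg$polarity == "POS" & reg$detected_rp, ]
  expect_equal(nrow(mt$matches) + nrow(mt$unmatched), nrow(reg_run))
})

test_that("features outside the ppm window are not matched", {
  tab <- tryptophan_table()
  tab$features$mz <- 205.110     # ~63 ppm away
  tab$areas <- tab$areas         # unchanged
  mt <- match_compounds(tab, read_registry(moint_registry_path()))
  expect_false("Tryptophan" %in% mt$matches$name)
  expect_equal(
    mt$unmatched$reason[mt$unmatched$name == "Tryptophan"],
    "no_mz_candidate")
})

test_that("ties break on smallest ppm error, then smallest RT error", {
  extra <- data.frame(feature_id = "F02", mz = 205.097 * (1 + 4e-6),
                      rt = 139, annotation = NA_character_,
                      stringsAsFactors = FALSE)
  tab <- tryptophan_table(extra)   # F01 at ~2.4 ppm, F02 at 4 ppm
  mt <- match_compounds(tab, read_registry(moint_registry_path()))
  expect_equal(mt$matches$feature_id[mt$matches$name == "Tryptophan"],
               "F01")
})

test_that("rt window failures are reported distinctly", {
  tab <- tryptophan_table()
  tab$features$rt <- 400
  mt <- match_compounds(tab, read_registry(moint_registry_path()))
  expect_equal(mt$unmatched$reason[mt$unmatched$name == "Tryptophan"],
               "rt_out_of_window")
})

test_that("polarity mismatch between table and registry errors", {
  reg <- read_registry(moint_registry_path())
  tab <- tryptophan_table()
  tab$samples$polarity <- "NEG"
  mt <- match_compounds(tab, reg)   # NEG records exist: works
  expect_true(is.data.frame(mt$matches))
  reg_pos <- reg[reg$polarity == "POS", ]
  class(reg_pos) <- class(reg)
  expect_error(match_compounds(tab, reg_pos), "no record for polarity")
})

test_that("normalization to the reference group follows the definition", {
  norm <- normalize_to_reference(list(I = c(10, 10, 10), III = c(20, 30)))
  expect_equal(norm$I, c(1, 1, 1))
  expect_equal(norm$III, c(2, 3))
  flagged <- normalize_to_reference(list(I = c(NA_real_, NA_real_),
                                         III = c(1, 2)))
  expect_length(flagged, 0)
  expect_equal(attr(flagged, "flag"), "NOT_NORMALIZABLE")
  expect_error(normalize_to_reference(list(III = c(1, 2))), "absent")
})

test_that("CV follows the sample-SD definition and its invariances", {
  expect_equal(cv_percent(c(10, 10, 10)), 0)
  expect_equal(cv_percent(c(8, 10, 12)), 20)   # sd = 2, mean = 10
  set.seed(14)
  for (i in 1:10) {
    x <- rlnorm(6); c_ <- runif(1, 0.1, 100)
    expect_equal(cv_percent(c_ * x), cv_percent(x), tolerance = 1e-10)
  }
  expect_error(cv_percent(c(5)), "two non-missing")
  expect_warning(v <- cv_percent(c(-1, 1)), "zero mean")
  expect_true(is.na(v))
})

test_that("a lipophilic compound lost in two-phase groups summarizes < 0.1", {
  cfg <- simulation_config(
    n_features = 0, base_cv = 0.1,
    registry = read_registry(moint_registry_path()),
    effects = list(effect_spec("lipophilic",
                               c("III", "IV", "III_B", "IV_B"),
                               fold_change = 0.02)),
    drift = drift_spec("NONE"), missing_below = 0, seed = 33)
  sim <- simulate_feature_table(cfg)
  mt <- match_compounds(sim$table, cfg$registry)
  sm <- summarize_compounds(sim$table, mt$matches)
  lip <- sm$compounds[sm$compounds$name == "3-Ketocholesterol", ]
  expect_lt(lip$mean_norm[lip$group == "III"], 0.1)
  expect_lt(lip$mean_norm[lip$group == "IV"], 0.1)
  expect_gt(lip$mean_norm[lip$group == "II"], 0.5)
})

test_that("an amino-acid fold gain lifts the aggregate above the reference", {
  cfg <- simulation_config(
    n_features = 0, base_cv = 0.1,
    registry = read_registry(moint_registry_path()),
    effects = list(effect_spec("subclass:Amino acids", c("III", "IV"),
                               fold_change = 2)),
    drift = drift_spec("NONE"), seed = 34)
  sim <- simulate_feature_table(cfg)
  mt <- match_compounds(sim$table, cfg$registry)
  sm <- summarize_compounds(sim$table, mt$matches)
  agg <- setNames(sm$aggregate$mean_of_means, sm$aggregate$group)
  expect_gt(agg[["III"]], agg[["I"]])
  expect_equal(agg[["I"]], 1, tolerance = 1e-9)
})

test_that("summaries are invariant to a global compound rescaling", {
  made <- make_drifted_table(n_feat = 3, n_per_group = 3, cv = 0.1,
                             drift_slope = 0, seed = 41)
  matches <- data.frame(name = "X", feature_id = "F01",
                        mz_error_ppm = 0, rt_error_s = 0,
                        stringsAsFactors = FALSE)
  s1 <- summarize_compounds(made$table, matches)
  made$table$areas <- made$table$areas * 7
  s2 <- summarize_compounds(made$table, matches)
  expect_equal(s2$compounds$mean_norm, s1$compounds$mean_norm,
               tolerance = 1e-12)
  expect_equal(s2$compounds$cv_pct, s1$compounds$cv_pct,
               tolerance = 1e-12)
})
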