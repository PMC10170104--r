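test_that("one-way ANOVA reproduces the hand-computed toy example", {
  res <- anova_oneway(list(c(1, 2, 3), c(5, 6, 7), c(9, 10, 11)))
  expect_equal(res$statistic, 48)       # SSB = 96, MSB = 48, MSW = 1
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)
  expect_equal(res$p_raw, pf(48, 2, 6, lower.tail = FALSE))
})

test_that("ANOVA handles degenerate and missing-value inputs", {
  res <- anova_oneway(list(c(2, 2, 2), c(2, 2, 2), c(2, 2, 2)))
  expect_true(res$degenerate)
  expect_equal(res$p_raw, 1)
  # separated constant groups: infinitely strong evidence
  res <- anova_oneway(list(c(1, 1), c(2, 2)))
  expect_equal(res$p_raw, 0)
  # NA dropped within groups
  res_na <- anova_oneway(list(c(1, 2, 3, NA), c(5, 6, 7), c(9, 10, 11)))
  expect_equal(res_na$statistic, 48)
  expect_error(anova_oneway(list(c(1, NA), c(2, 3))), ">= 2 non-missing")
})

test_that("ANOVA on two equal-variance groups matches the pooled t test", {
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(5, 1)
    res <- anova_oneway(list(a, b))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p_raw, tt$p.value, tolerance = 1e-9)
  }
})

test_that("Welch t matches an independent formula evaluation to 1e-10", {
  cases <- list(list(a = c(1, 2, 3), b = c(1, 2, 3, 4, 5)),
                list(a = c(10, 12, 9, 14), b = c(20, 25, 30)),
                list(a = rnorm(8, 0, 1), b = rnorm(5, 1, 3)))
  set.seed(5)
  for (cs in cases) {
    got <- welch_t(cs$a, cs$b)
    want <- welch_oracle(cs$a, cs$b)
    expect_equal(got$statistic, want$t, tolerance = 1e-10)
    expect_equal(got$df1, want$df, tolerance = 1e-10)
    expect_equal(got$p_raw, want$p, tolerance = 1e-10)
  }
})

test_that("Welch t identity and degenerate cases", {
  res <- welch_t(c(4, 5, 6), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_raw, 1)
  res <- welch_t(c(3, 3, 3), c(3, 3))
  expect_true(res$degenerate)
  expect_equal(res$p_raw, 1)
  res <- welch_t(c(3, 3, 3), c(5, 5))
  expect_equal(res$p_raw, 0)
})

test_that("Welch t keeps its nominal type-I error under unequal variances", {
  set.seed(202)
  n_rep <- 4000
  rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    a <- rnorm(10, 0, 1); b <- rnorm(5, 0, 3)
    rej[i] <- welch_t(a, b)$p_raw < 0.05
  }
  expect_gte(mean(rej), 0.040)
  expect_lte(mean(rej), 0.060)
})

test_that("Bonferroni definition, cap, monotonicity and m handling", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 3), 1.0)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "at least the number")
  set.seed(3)
  p <- runif(50)
  adj <- bonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_equal(order(adj[order(p)]), seq_along(p))  # order preserving
})

test_that("significance categories reproduce the star-legend bins", {
  expect_equal(significance_category(0.03), "*")
  expect_equal(significance_category(0.2), "ns")
  expect_equal(significance_category(5e-5), "****")
  # boundaries are half-open: the threshold itself is not significant
  expect_equal(significance_category(c(0.05, 0.049999, 0.01, 0.0099,
                                       0.001, 0.0001, 0.00009)),
               c("ns", "*", "*", "**", "**", "***", "****"))
})

test_that("row-wise ANOVA agrees with the scalar implementation", {
  set.seed(8)
  mat <- matrix(rlnorm(40 * 18), 40, 18)
  mat[sample(length(mat), 30)] <- NA
  groups <- rep(c("I", "II", "III"), each = 6)
  rows <- anova_rows(mat, groups)
  for (i in c(1, 7, 19, 40)) {
    gs <- split(mat[i, ], groups)
    if (any(vapply(gs, function(g) sum(!is.na(g)), 0L) < 2)) {
      expect_true(is.na(rows$p_raw[i]))
    } else {
      ref <- anova_oneway(gs)
      expect_equal(rows$statistic[i], ref$statistic, tolerance = 1e-9)
      expect_equal(rows$p_raw[i], ref$p_raw, tolerance = 1e-9)
    }
  }
})

test_that("null two-group ANOVA rejects at close to the nominal rate", {
  set.seed(77)
  mat <- matrix(rnorm(10000 * 10), 10000, 10)
  p <- anova_rows(mat, rep(c("I", "II"), each = 5))$p_raw
  expect_gte(mean(p < 0.05), 0.040)
  expect_lte(mean(p < 0.05), 0.060)
})

test_that("detected-feature counting applies the detection rule", {
  areas <- rbind(c(NA, 5, 0, 3),
                 c(1, NA, NA, 0),
                 c(2, 2, 2, 2))
  tab <- make_tiny_table(areas, groups = c(I = 2, III = 2))
  fc <- count_detected_features(tab)
  expect_equal(fc$per_sample$count, c(2, 2, 1, 2))
  # noiseless complete table: every count equals the feature number
  tab2 <- make_tiny_table(matrix(5, 4, 4), groups = c(I = 2, III = 2))
  expect_true(all(count_detected_features(tab2)$per_sample$count == 4))
})

test_that("feature counting produces the configured group contrasts", {
  set.seed(9)
  groups <- c(I = 3, II = 3, III = 3, IV = 3, III_B = 3, IV_B = 3)
  areas <- matrix(rlnorm(20 * 18), 20, 18)
  tab <- make_tiny_table(areas, groups = groups)
  fc <- count_detected_features(tab)
  expect_setequal(fc$contrasts$contrast,
                  c("II vs I", "III vs I", "IV vs I", "III_B vs III",
                    "IV_B vs IV"))
  expect_equal(fc$anova$df1, 5)
  expect_equal(nrow(fc$per_group), 6)
})

test_that("whole-table screen skips features with too few values", {
  areas <- rbind(c(1, 2, 3, 10, 11, 12), c(NA, NA, 1, 2, 3, 4))
  tab <- make_tiny_table(areas, groups = c(I = 3, III = 3))
  sc <- feature_anova_screen(tab)
  expect_false(is.na(sc$p_raw[1]))
  expect_true(is.na(sc$p_raw[2]))
  expect_true(all(sc$p_adj >= sc$p_raw, na.rm = TRUE))
})
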