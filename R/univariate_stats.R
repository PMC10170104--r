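#' One-way fixed-effects ANOVA
#'
#' Classical one-way analysis of variance across two or more groups, the
#' per-feature screening test used throughout the pipeline. Missing values
#' are dropped within each group. When both the between- and within-group
#' sums of squares are zero the test is degenerate and reported with
#' p = 1 and `degenerate = TRUE`; when only the within-group sum is zero
#' but the groups differ, F is infinite and p = 0.
#'
#' @param groups a list of numeric vectors, one per group; each group needs
#'   at least two non-missing values.
#' @param unit_id,contrast identifiers carried into the result.
#' @return a one-row data.frame (a `TestResult`): `unit_id`, `contrast`,
#'   `statistic`, `df1`, `df2`, `p_raw`, `p_adj` (initially equal to
#'   `p_raw`), `category`, `degenerate`.
#' @export
anova_oneway <- function(groups, unit_id = NA_character_,
                         contrast = "ANOVA") {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2) stop("one-way ANOVA needs at least two groups")
  n_i <- lengths(groups)
  if (any(n_i < 2))
    stop("every group needs >= 2 non-missing values; got sizes ",
         paste(n_i, collapse = ", "))
  k <- length(groups)
  n <- sum(n_i)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(n_i * means) / n
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1
  df2 <- n - k
  degenerate <- FALSE
  if (ssw <= 0 && ssb <= 0) {
    f <- 0; p <- 1; degenerate <- TRUE
  } else if (ssw <= 0) {
    f <- Inf; p <- 0
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  test_result(unit_id, contrast, f, df1, df2, p, degenerate)
}

#' Welch's two-sample t test
#'
#' Unequal-variance two-sided t test with Welch-Satterthwaite degrees of
#' freedom, used for every pairwise contrast against the reference
#' extraction. Two constant, equal samples give t = 0 and p = 1 (degenerate
#' flag set).
#'
#' @param a,b numeric vectors with at least two non-missing values each.
#' @param unit_id,contrast identifiers carried into the result.
#' @return a one-row `TestResult` data.frame; `df1` holds the
#'   Welch-Satterthwaite df and `df2` is `NA`.
#' @export
welch_t <- function(a, b, unit_id = NA_character_, contrast = NA_character_) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("Welch's t test needs >= 2 non-missing values per sample")
  va <- stats::var(a); vb <- stats::var(b)
  if (va <= 0 && vb <= 0) {
    if (mean(a) == mean(b)) {
      return(test_result(unit_id, contrast, 0, NA_real_, NA_real_, 1, TRUE))
    }
    # zero variance but different means: infinitely strong evidence
    return(test_result(unit_id, contrast,
                       sign(mean(a) - mean(b)) * Inf, NA_real_, NA_real_, 0,
                       FALSE))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  test_result(unit_id, contrast, unname(ht$statistic),
              unname(ht$parameter), NA_real_, ht$p.value, FALSE)
}

test_result <- function(unit_id, contrast, statistic, df1, df2, p_raw,
                        degenerate = FALSE, p_adj = p_raw) {
  data.frame(unit_id = unit_id, contrast = contrast, statistic = statistic,
             df1 = df1, df2 = df2, p_raw = p_raw, p_adj = p_adj,
             category = significance_category(p_adj),
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Bonferroni family-wise error correction
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param m number of tests in the family; defaults to `length(p)` and must
#'   not be smaller.
#' @return `pmin(1, m * p)`, order preserving.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  if (m < length(p))
    stop("m (", m, ") must be at least the number of p-values (",
         length(p), ")")
  pmin(1, m * p)
}

#' Significance category of a p-value
#'
#' Standard star notation on half-open bins: `ns` for p >= 0.05, `*` for
#' p < 0.05, `**` for p < 0.01, `***` for p < 0.001 and `****` for
#' p < 0.0001.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return character vector of categories.
#' @export
significance_category <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- "ns"
  out[ok & p < 0.05] <- "*"
  out[ok & p < 0.01] <- "**"
  out[ok & p < 0.001] <- "***"
  out[ok & p < 0.0001] <- "****"
  out
}

#' Row-wise one-way ANOVA over a matrix
#'
#' Vectorized equivalent of applying [anova_oneway()] to every row of an
#' area matrix (features x samples), used for whole-table feature screening
#' and for the simulation-based error-rate checks where per-row loops would
#' be too slow. Rows where any group has fewer than two non-missing values
#' get `NA` (skipped, not imputed).
#'
#' @param mat numeric matrix, units x samples; `NA` allowed.
#' @param groups factor/character vector of length `ncol(mat)`.
#' @return data.frame with `statistic`, `df1`, `df2`, `p_raw` per row.
#' @export
anova_rows <- function(mat, groups) {
  groups <- as.factor(as.character(groups))
  if (ncol(mat) != length(groups))
    stop("groups must have one label per matrix column")
  k <- nlevels(groups)
  if (k < 2) stop("need at least two groups")
  G <- stats::model.matrix(~ 0 + groups)          # samples x k indicator
  obs <- !is.na(mat)
  x <- mat; x[!obs] <- 0
  n_i <- obs %*% G                                 # rows x k counts
  s_i <- x %*% G                                   # rows x k sums
  ss_i <- (x * x) %*% G
  ok <- rowSums(n_i >= 2) == k
  n <- rowSums(n_i)
  m_i <- s_i / n_i
  grand <- rowSums(s_i) / n
  ssb <- rowSums(n_i * (m_i - grand)^2)
  ssw <- rowSums(ss_i - n_i * m_i^2)
  ssw <- pmax(ssw, 0)                              # guard fp cancellation
  df1 <- k - 1
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  zero_w <- ssw <= 0
  p[zero_w & ssb > 0] <- 0
  f[zero_w & ssb > 0] <- Inf
  p[zero_w & ssb <= 0] <- 1
  f[zero_w & ssb <= 0] <- 0
  f[!ok] <- NA_real_; p[!ok] <- NA_real_
  data.frame(statistic = f, df1 = df1, df2 = ifelse(ok, df2, NA_real_),
             p_raw = p, row.names = rownames(mat))
}

default_count_contrasts <- list(
  c("II", "I"), c("III", "I"), c("IV", "I"),
  c("III_B", "III"), c("IV_B", "IV"))

#' Count detected features per sample and compare groups
#'
#' A feature is "detected" in a sample when its area satisfies the
#' detection rule (default: non-missing and strictly positive; zero and
#' missing are both non-detections). Counts are summarized per group and
#' compared with a one-way ANOVA over all study groups plus Welch contrasts
#' (by default each alternative extraction vs the reference and each
#' bead-homogenized variant vs its base method).
#'
#' @param table a `FeatureTable`.
#' @param rule function mapping an area vector to a logical detection
#'   vector; the default is `function(a) !is.na(a) & a > 0`.
#' @param contrasts list of `c(group, reference)` pairs for Welch tests.
#' @return a list of class `FeatureCountResult`: `per_sample` (data.frame
#'   sample_id, group, count), `per_group` (group, n, mean, sd), `anova`
#'   and `contrasts` (`TestResult` rows).
#' @export
count_detected_features <- function(table,
                                    rule = function(a) !is.na(a) & a > 0,
                                    contrasts = default_count_contrasts) {
  validate_feature_table(table)
  det <- apply(table$areas, 2, rule)
  if (is.null(dim(det))) det <- matrix(det, nrow = 1)
  counts <- colSums(det)
  per_sample <- data.frame(sample_id = table$samples$sample_id,
                           group = table$samples$group,
                           count = as.integer(counts),
                           stringsAsFactors = FALSE)
  study <- per_sample[table$samples$sample_type == "STUDY", ]
  grp <- split(study$count, study$group)
  per_group <- data.frame(
    group = names(grp),
    n = lengths(grp),
    mean = vapply(grp, mean, numeric(1)),
    sd = vapply(grp, stats::sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  aov_res <- if (length(grp) >= 2 && all(lengths(grp) >= 2))
    anova_oneway(grp, unit_id = "feature_count") else NULL
  ctr <- lapply(contrasts, function(cc) {
    if (!all(cc %in% names(grp))) return(NULL)
    if (length(grp[[cc[1]]]) < 2 || length(grp[[cc[2]]]) < 2) return(NULL)
    welch_t(grp[[cc[1]]], grp[[cc[2]]], unit_id = "feature_count",
            contrast = paste(cc[1], "vs", cc[2]))
  })
  ctr <- do.call(rbind, ctr[!vapply(ctr, is.null, logical(1))])
  structure(list(per_sample = per_sample, per_group = per_group,
                 anova = aov_res, contrasts = ctr),
            class = "FeatureCountResult")
}

#' Per-feature group screening over a whole table
#'
#' Runs the row-wise one-way ANOVA across the study groups of a table,
#' applies Bonferroni correction over the testable features and attaches
#' significance categories. QC samples are excluded.
#'
#' @param table a `FeatureTable`.
#' @param log_transform test on `log(area)` instead of raw areas
#'   (off by default; raw corrected peak areas are the conventional scale
#'   here).
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return data.frame with one row per feature: `unit_id`, `statistic`,
#'   `df1`, `df2`, `p_raw`, `p_adj`, `category`.
#' @export
feature_anova_screen <- function(table, log_transform = FALSE,
                                 adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  validate_feature_table(table)
  keep <- table$samples$sample_type == "STUDY"
  mat <- table$areas[, keep, drop = FALSE]
  if (log_transform) mat <- log(mat)
  res <- anova_rows(mat, table$samples$group[keep])
  ok <- !is.na(res$p_raw)
  res$p_adj <- res$p_raw
  if (adjust == "bonferroni" && any(ok))
    res$p_adj[ok] <- bonferroni(res$p_raw[ok])
  res$category <- significance_category(res$p_adj)
  data.frame(unit_id = table$features$feature_id, res,
             row.names = NULL, stringsAsFactors = FALSE)
}
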