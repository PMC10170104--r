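#' Coefficient of variation in percent
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean,
#' times 100: the study's precision metric. Scale invariant; undefined
#' (returned as `NA` with a warning) when the mean is zero.
#'
#' @param values numeric vector with at least two non-missing values.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("CV needs at least two non-missing values")
  m <- mean(values)
  if (m == 0) {
    warning("CV undefined for zero mean")
    return(NA_real_)
  }
  100 * stats::sd(values) / m
}

registry_for_run <- function(registry, column, polarity) {
  reg <- registry[registry$polarity == polarity, , drop = FALSE]
  det <- if (column == "RP_PHENYL_HEXYL") reg$detected_rp else
    reg$detected_hilic
  reg <- reg[det, , drop = FALSE]
  reg$rt_run <- if (column == "RP_PHENYL_HEXYL") reg$rt_rp else reg$rt_hilic
  reg
}

#' Match registry compounds to features
#'
#' Each compound detected on the table's analytical run is matched to the
#' feature closest in m/z within a ppm window, requiring the retention time
#' to fall within an absolute window. Ties are broken by smallest absolute
#' ppm error, then smallest absolute RT error. Compounds flagged "not
#' detected" for the run are skipped; unmatched compounds are reported
#' with the reason.
#'
#' @param table a `FeatureTable` (single analytical run).
#' @param registry a `CompoundRegistry`.
#' @param mz_tol_ppm m/z tolerance in parts per million (default 5, the
#'   usual Orbitrap precursor tolerance).
#' @param rt_tol_s retention-time tolerance in seconds (default 10).
#' @return list with `matches` (data.frame: name, feature_id,
#'   mz_error_ppm, rt_error_s) and `unmatched` (data.frame: name, reason
#'   in `no_mz_candidate` / `rt_out_of_window`).
#' @export
match_compounds <- function(table, registry, mz_tol_ppm = 5, rt_tol_s = 10) {
  validate_feature_table(table)
  run <- unique(table$samples[, c("column", "polarity")])
  if (nrow(run) != 1)
    stop("table spans more than one analytical run")
  if (!any(registry$polarity == run$polarity))
    stop("registry has no record for polarity ", run$polarity)
  reg <- registry_for_run(registry, run$column, run$polarity)
  feat <- table$features
  matches <- list(); unmatched <- list()
  for (i in seq_len(nrow(reg))) {
    ppm <- (feat$mz - reg$mz[i]) / reg$mz[i] * 1e6
    cand <- which(abs(ppm) <= mz_tol_ppm)
    if (!length(cand)) {
      unmatched[[length(unmatched) + 1]] <-
        data.frame(name = reg$name[i], reason = "no_mz_candidate",
                   stringsAsFactors = FALSE)
      next
    }
    rt_err <- feat$rt[cand] - reg$rt_run[i]
    in_rt <- abs(rt_err) <= rt_tol_s
    if (!any(in_rt)) {
      unmatched[[length(unmatched) + 1]] <-
        data.frame(name = reg$name[i], reason = "rt_out_of_window",
                   stringsAsFactors = FALSE)
      next
    }
    cand <- cand[in_rt]; rt_err <- rt_err[in_rt]
    o <- order(abs(ppm[cand]), abs(rt_err))
    pick <- o[1]
    matches[[length(matches) + 1]] <-
      data.frame(name = reg$name[i], feature_id = feat$feature_id[cand[pick]],
                 mz_error_ppm = ppm[cand[pick]], rt_error_s = rt_err[pick],
                 stringsAsFactors = FALSE)
  }
  empty_m <- data.frame(name = character(), feature_id = character(),
                        mz_error_ppm = numeric(), rt_error_s = numeric(),
                        stringsAsFactors = FALSE)
  empty_u <- data.frame(name = character(), reason = character(),
                        stringsAsFactors = FALSE)
  list(matches = if (length(matches)) do.call(rbind, matches) else empty_m,
       unmatched = if (length(unmatched)) do.call(rbind, unmatched) else
         empty_u)
}

#' Normalize group-wise areas to a reference extraction
#'
#' Divides every area by the mean area of the reference group, so the
#' reference group's mean normalized area is exactly 1 and other groups
#' are expressed as recovery relative to the reference.
#'
#' @param areas_by_group named list of numeric vectors (one per group).
#' @param reference reference group label (default `"I"`).
#' @return named list of normalized vectors, or `NULL` (flagged
#'   `NOT_NORMALIZABLE` via attribute) when the reference mean is zero or
#'   all-missing.
#' @export
normalize_to_reference <- function(areas_by_group, reference = "I") {
  if (!reference %in% names(areas_by_group))
    stop("reference group '", reference, "' absent")
  ref <- areas_by_group[[reference]]
  ref <- ref[!is.na(ref)]
  if (!length(ref) || mean(ref) == 0)
    return(structure(list(), flag = "NOT_NORMALIZABLE"))
  lapply(areas_by_group, function(v) v / mean(ref))
}

#' Summarize matched compounds across extraction groups
#'
#' For every matched compound: per-group mean normalized area (reference
#' mean = 1), standard deviation and CV of the normalized areas, plus a
#' Welch t test of each non-reference group against the reference on the
#' raw areas. Also returns the panel-level aggregate: per group, the mean
#' over compounds of the per-group normalized means with its SD, and the
#' mean compound CV.
#'
#' @param table a `FeatureTable`.
#' @param matches the `matches` data.frame from [match_compounds()].
#' @param reference reference group label.
#' @return list with `compounds` (data.frame: name, group, n, mean_norm,
#'   sd_norm, cv_pct, p_raw, p_adj, category vs reference),
#'   `not_normalizable` (character) and `aggregate` (data.frame: group,
#'   mean_of_means, sd_of_means, mean_cv_pct).
#' @export
summarize_compounds <- function(table, matches, reference = "I") {
  validate_feature_table(table)
  study <- table$samples$sample_type == "STUDY"
  groups <- table$samples$group[study]
  rows <- list(); skipped <- character(0)
  for (i in seq_len(nrow(matches))) {
    fid <- matches$feature_id[i]
    v <- table$areas[fid, study]
    by_g <- split(v, groups)
    norm <- normalize_to_reference(by_g, reference)
    if (!length(norm)) {
      skipped <- c(skipped, matches$name[i])
      next
    }
    ref_v <- by_g[[reference]]
    for (g in names(norm)) {
      nv <- norm[[g]]; nv_ok <- nv[!is.na(nv)]
      gv <- by_g[[g]]
      test <- if (g != reference && sum(!is.na(gv)) >= 2 &&
                    sum(!is.na(ref_v)) >= 2)
        welch_t(gv, ref_v, unit_id = matches$name[i],
                contrast = paste(g, "vs", reference)) else NULL
      rows[[length(rows) + 1]] <- data.frame(
        name = matches$name[i], group = g, n = length(nv_ok),
        mean_norm = if (length(nv_ok)) mean(nv_ok) else NA_real_,
        sd_norm = if (length(nv_ok) >= 2) stats::sd(nv_ok) else NA_real_,
        cv_pct = if (length(nv_ok) >= 2 && mean(nv_ok) != 0)
          cv_percent(nv_ok) else NA_real_,
        p_raw = if (is.null(test)) NA_real_ else test$p_raw,
        category = if (is.null(test)) NA_character_ else test$category,
        stringsAsFactors = FALSE)
    }
  }
  compounds <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), group = character(), n = integer(),
               mean_norm = numeric(), sd_norm = numeric(),
               cv_pct = numeric(), p_raw = numeric(),
               category = character(), stringsAsFactors = FALSE)
  agg <- NULL
  if (nrow(compounds)) {
    by_g <- split(compounds, compounds$group)
    agg <- do.call(rbind, lapply(by_g, function(d) data.frame(
      group = d$group[1],
      mean_of_means = mean(d$mean_norm, na.rm = TRUE),
      sd_of_means = stats::sd(d$mean_norm, na.rm = TRUE),
      mean_cv_pct = mean(d$cv_pct, na.rm = TRUE),
      stringsAsFactors = FALSE)))
    rownames(agg) <- NULL
  }
  list(compounds = compounds, not_normalizable = skipped, aggregate = agg)
}
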