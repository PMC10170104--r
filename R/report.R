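ARROWS <- c("↘↘", "↘", "→", "↗", "↗↗")

#' Ordinal arrow for a metric ratio
#'
#' Maps the ratio of a group metric to the cross-group median onto the
#' five-level arrow scale used in the final decision matrix. Bands (upper
#' bound inclusive, so a value exactly on a threshold falls in the lower
#' band): ratio <= 0.5 gives a strong decrease, (0.5, 0.9] a decrease,
#' (0.9, 1.1] unchanged, (1.1, 2] an increase, > 2 a strong increase.
#'
#' @param ratio positive metric ratio(s).
#' @param bands the four interior thresholds.
#' @return character vector of arrows.
#' @export
arrow_for_ratio <- function(ratio, bands = c(0.5, 0.9, 1.1, 2.0)) {
  stopifnot(length(bands) == 4, !is.unsorted(bands))
  idx <- findInterval(ratio, bands, left.open = TRUE) + 1L
  ARROWS[idx]
}

#' Build the per-method decision matrix
#'
#' Condenses the evaluation into one scorecard per extraction group: mean
#' detected-feature count, mean normalized panel (MoInt) area and mean
#' panel CV, each expressed as a ratio to the cross-group median and as an
#' ordinal arrow. The matrix is qualitative by design; no composite score
#' is computed.
#'
#' @param feature_counts a `FeatureCountResult` from
#'   [count_detected_features()].
#' @param compound_summaries result of [summarize_compounds()].
#' @param reference reference group label (must be present).
#' @param bands arrow thresholds, see [arrow_for_ratio()].
#' @return data.frame of class `MethodScorecard`: group, the three raw
#'   metrics, their ratios to the median, and their arrows.
#' @export
build_scorecards <- function(feature_counts, compound_summaries,
                             reference = "I",
                             bands = c(0.5, 0.9, 1.1, 2.0)) {
  fc <- feature_counts$per_group
  agg <- compound_summaries$aggregate
  if (is.null(agg)) stop("compound summaries carry no aggregate")
  groups <- sort(unique(fc$group))
  missing <- setdiff(c(reference, agg$group), groups)
  if (length(missing))
    stop("missing group(s) in feature counts: ",
         paste(missing, collapse = ", "))
  missing <- setdiff(groups, agg$group)
  if (length(missing))
    stop("missing group(s) in compound summaries: ",
         paste(missing, collapse = ", "))
  sc <- data.frame(group = groups, stringsAsFactors = FALSE)
  sc$feature_count <- fc$mean[match(groups, fc$group)]
  sc$moint_area <- agg$mean_of_means[match(groups, agg$group)]
  sc$moint_cv_pct <- agg$mean_cv_pct[match(groups, agg$group)]
  for (metric in c("feature_count", "moint_area", "moint_cv_pct")) {
    ratio <- sc[[metric]] / stats::median(sc[[metric]])
    sc[[paste0(metric, "_ratio")]] <- ratio
    sc[[paste0(metric, "_arrow")]] <- arrow_for_ratio(ratio, bands)
  }
  class(sc) <- c("MethodScorecard", "data.frame")
  sc
}

#' Run the full extraction-evaluation pipeline
#'
#' Executes drift correction, detected-feature counting, targeted panel
#' evaluation, ANOVA-gated PC-DFA with Monte Carlo cross-validation,
#' pathway analysis of the matched panel compounds, and the decision
#' matrix, collecting every stage result and the parameter provenance in
#' one bundle. Any stage failure aborts with the stage name.
#'
#' @param table a `FeatureTable`.
#' @param registry a `CompoundRegistry` for the targeted stage.
#' @param pathway_library optional pathway library for enrichment (skipped
#'   when `NULL`).
#' @param reference reference extraction group.
#' @param alpha significance level for the ANOVA feature gate.
#' @param mz_tol_ppm,rt_tol_s compound-matching tolerances.
#' @param skip_correction bypass QC drift correction (required explicitly
#'   when the table has no QC samples).
#' @param mccv_iter,test_fraction Monte Carlo cross-validation settings.
#' @param seed integer seed for the cross-validation splits.
#' @param out_dir optional directory; when given, all stage results are
#'   written there as CSV plus a `parameters.json` provenance file.
#' @return a list bundle with elements `corrected`, `drift_fits`,
#'   `feature_counts`, `matches`, `compound_summaries`, `selected_features`,
#'   `pcdfa`, `mccv`, `pathways`, `scorecards`, `parameters`.
#' @export
run_pipeline <- function(table, registry, pathway_library = NULL,
                         reference = "I", alpha = 0.05,
                         mz_tol_ppm = 5, rt_tol_s = 10,
                         skip_correction = FALSE,
                         mccv_iter = 200, test_fraction = 0.3, seed = 1L,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  params <- list(reference = reference, alpha = alpha,
                 mz_tol_ppm = mz_tol_ppm, rt_tol_s = rt_tol_s,
                 skip_correction = skip_correction, mccv_iter = mccv_iter,
                 test_fraction = test_fraction, seed = seed,
                 drift_smoother = "lowess on log area, span max(0.5, 4/nQC)")
  if (skip_correction) {
    corrected <- table; fits <- NULL
  } else {
    cr <- stage("correct", correct_table(table))
    corrected <- cr$table; fits <- cr$fits
  }
  counts <- stage("stats", count_detected_features(corrected))
  mt <- stage("targeted", match_compounds(corrected, registry,
                                          mz_tol_ppm, rt_tol_s))
  summaries <- stage("targeted",
                     summarize_compounds(corrected, mt$matches, reference))
  sel <- stage("pcdfa", select_features_anova(corrected, alpha))
  model <- NULL; cv <- NULL
  study <- corrected$samples$sample_type == "STUDY"
  if (length(sel) >= 2) {
    x <- t(corrected$areas[sel, study, drop = FALSE])
    x[is.na(x)] <- 0       # undetected = below limit for the projection
    labels <- corrected$samples$group[study]
    model <- stage("pcdfa", fit_pcdfa(x, labels))
    if (mccv_iter >= 1)
      cv <- stage("pcdfa", mccv(x, labels, n_iter = mccv_iter,
                                test_fraction = test_fraction, seed = seed))
  }
  pw <- NULL
  if (!is.null(pathway_library)) {
    kegg <- registry$kegg_id[match(mt$matches$name, registry$name)]
    kegg <- unique(kegg[!is.na(kegg)])
    pw <- stage("pathways",
                suppressWarnings(analyze_pathways(kegg, pathway_library)))
  }
  cards <- stage("report", build_scorecards(counts, summaries, reference))
  bundle <- list(corrected = corrected, drift_fits = fits,
                 feature_counts = counts, matches = mt,
                 compound_summaries = summaries, selected_features = sel,
                 pcdfa = model, mccv = cv, pathways = pw,
                 scorecards = cards, parameters = params)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) if (!is.null(x))
    utils::write.csv(x, file.path(out_dir, name), row.names = FALSE)
  wr(bundle$drift_fits, "drift_fits.csv")
  wr(bundle$feature_counts$per_sample, "feature_counts_per_sample.csv")
  wr(bundle$feature_counts$per_group, "feature_counts_per_group.csv")
  wr(bundle$feature_counts$contrasts, "feature_count_contrasts.csv")
  wr(bundle$matches$matches, "compound_matches.csv")
  wr(bundle$matches$unmatched, "compound_unmatched.csv")
  wr(bundle$compound_summaries$compounds, "compound_summaries.csv")
  wr(bundle$compound_summaries$aggregate, "compound_aggregate.csv")
  if (!is.null(bundle$pcdfa)) {
    df <- bundle$pcdfa$df_scores
    colnames(df) <- paste0("DF", seq_len(ncol(df)))
    wr(data.frame(sample_id = rownames(df),
                  group = as.character(bundle$pcdfa$labels), df,
                  stringsAsFactors = FALSE), "df_scores.csv")
  }
  if (!is.null(bundle$mccv))
    wr(as.data.frame(bundle$mccv$confusion), "mccv_confusion.csv")
  wr(as.data.frame(bundle$pathways), "pathway_results.csv")
  wr(as.data.frame(unclass(bundle$scorecards)), "scorecards.csv")
  jsonlite::write_json(bundle$parameters,
                       file.path(out_dir, "parameters.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
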