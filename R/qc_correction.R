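#' Fit a per-feature drift curve from pooled-QC injections
#'
#' Repeated injections of the pooled QC sample trace the instrument's
#' intensity drift for each feature. The drift is modelled multiplicatively:
#' a smoother (locally weighted regression of log area on injection order,
#' QC-RLSC style) is fit through the QC points, back-transformed, evaluated
#' at every injection order by linear interpolation with constant
#' extrapolation beyond the first/last QC, and normalized so its median
#' over the QC injections is 1. With fewer than five QC points a straight
#' line on the log scale is used; with fewer than two the curve degrades to
#' the identity (`NONE`) and a warning is issued.
#'
#' @param qc_orders integer injection orders of the QC injections.
#' @param qc_areas areas at those injections (`NA` allowed).
#' @param eval_orders injection orders at which the curve is needed.
#' @param method `"lowess"` (default smoother), `"linear"` or `"none"`.
#' @param min_qc minimum usable QC points for a non-identity fit.
#' @return a `DriftFit` list: `method` (`"LOWESS"`, `"LINEAR"` or
#'   `"NONE"`), `curve` (positive multiplier per `eval_orders` entry),
#'   `qc_cv_before` and `qc_cv_after` in percent.
#' @export
fit_drift <- function(qc_orders, qc_areas, eval_orders = qc_orders,
                      method = c("lowess", "linear", "none"), min_qc = 2) {
  method <- match.arg(method)
  ok <- !is.na(qc_areas) & qc_areas > 0
  x <- qc_orders[ok]; y <- qc_areas[ok]
  identity_fit <- function(used) {
    cv <- if (length(y) >= 2) cv_percent(y) else NA_real_
    list(method = used, curve = rep(1, length(eval_orders)),
         qc_cv_before = cv, qc_cv_after = cv)
  }
  if (method == "none") return(identity_fit("NONE"))
  if (length(x) < max(2, min_qc)) {
    warning("fewer than ", max(2, min_qc),
            " usable QC points; returning identity drift curve")
    return(identity_fit("NONE"))
  }
  ly <- log(y)
  if (method == "lowess" && length(x) >= 5) {
    span <- max(0.5, 4 / length(x))
    sm <- stats::lowess(x, ly, f = min(span, 1))
    fx <- sm$x; fy <- sm$y
    used <- "LOWESS"
  } else {
    fit <- stats::lm.fit(cbind(1, x), ly)
    fx <- x; fy <- fit$coefficients[1] + fit$coefficients[2] * x
    used <- "LINEAR"
  }
  curve_at <- function(orders)
    exp(stats::approx(fx, fy, xout = orders, rule = 2, ties = mean)$y)
  qc_curve <- curve_at(x)
  scale <- stats::median(qc_curve)
  curve <- curve_at(eval_orders) / scale
  list(method = used, curve = pmax(curve, .Machine$double.eps),
       qc_cv_before = cv_percent(y),
       qc_cv_after = cv_percent(y / (qc_curve / scale)))
}

#' Pooled-QC drift correction of a feature table
#'
#' Divides every feature's areas by its fitted drift curve evaluated at
#' each sample's injection order. Missing areas stay missing; QC samples
#' are corrected too and retained so the residual QC variability can be
#' inspected. Features without enough usable QC points fall back to the
#' identity curve (method `NONE`) and pass through unchanged.
#'
#' @param table a `FeatureTable` containing at least one QC sample.
#' @param method,min_qc forwarded to [fit_drift()].
#' @return list with `table` (corrected `FeatureTable`) and `fits`
#'   (data.frame: feature_id, method, qc_cv_before, qc_cv_after).
#' @export
correct_table <- function(table, method = c("lowess", "linear", "none"),
                          min_qc = 2) {
  method <- match.arg(method)
  validate_feature_table(table)
  is_qc <- table$samples$sample_type == "QC"
  if (!any(is_qc))
    stop("table has no QC samples; re-run with drift correction ",
         "explicitly skipped if this is intended")
  orders <- table$samples$injection_order
  qc_ord <- orders[is_qc]
  out <- table$areas
  fits <- vector("list", nrow(table$features))
  for (i in seq_len(nrow(table$features))) {
    fit <- withCallingHandlers(
      fit_drift(qc_ord, table$areas[i, is_qc], eval_orders = orders,
                method = method, min_qc = min_qc),
      warning = function(w) invokeRestart("muffleWarning"))
    out[i, ] <- table$areas[i, ] / fit$curve
    fits[[i]] <- data.frame(feature_id = table$features$feature_id[i],
                            method = fit$method,
                            qc_cv_before = fit$qc_cv_before,
                            qc_cv_after = fit$qc_cv_after,
                            stringsAsFactors = FALSE)
  }
  corrected <- table
  corrected$areas <- out
  validate_feature_table(corrected)
  list(table = corrected, fits = do.call(rbind, fits))
}
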