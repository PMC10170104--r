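#' ANOVA-gated feature selection for multivariate analysis
#'
#' Keeps the features whose Bonferroni-adjusted one-way ANOVA p-value
#' across the study groups falls below `alpha` — i.e. the features showing
#' a significant difference between any two extraction groups. QC samples
#' are excluded.
#'
#' @param table a `FeatureTable`.
#' @param alpha significance level (default 0.05).
#' @return character vector of selected feature ids (possibly empty).
#' @export
select_features_anova <- function(table, alpha = 0.05) {
  screen <- feature_anova_screen(table)
  sel <- screen$unit_id[!is.na(screen$p_adj) & screen$p_adj < alpha]
  if (!length(sel))
    message("no feature passed the ANOVA gate at alpha = ", alpha)
  sel
}

# Fisher discriminant axes on a scores matrix; returns projection matrix
# (p x d) and class centroids in discriminant space.
fisher_lda <- function(scores, labels, ridge = 1e-8) {
  labels <- factor(labels)
  k <- nlevels(labels)
  p <- ncol(scores)
  grand <- colMeans(scores)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (g in levels(labels)) {
    xg <- scores[labels == g, , drop = FALSE]
    mg <- colMeans(xg)
    xc <- sweep(xg, 2, mg)
    Sw <- Sw + crossprod(xc)
    Sb <- Sb + nrow(xg) * tcrossprod(mg - grand)
  }
  Sw <- Sw + diag(ridge * max(sum(diag(Sw)), 1), p)
  eg <- eigen(solve(Sw, Sb))
  d <- min(k - 1, p)
  W <- Re(eg$vectors[, seq_len(d), drop = FALSE])
  df <- scores %*% W
  centroids <- do.call(rbind, lapply(levels(labels), function(g)
    colMeans(df[labels == g, , drop = FALSE])))
  rownames(centroids) <- levels(labels)
  list(W = W, centroids = centroids, scores = df)
}

#' Fit a PC-DFA model
#'
#' Principal component analysis of the column-centered (unscaled) data
#' matrix by singular value decomposition, retention of components by the
#' Kaiser criterion with a floor of two components, and Fisher linear
#' discriminant analysis on the retained component scores. Because the
#' data are centered but not scaled to unit variance, the Kaiser rule is
#' applied in its Kaiser-Guttman generalization by default: retain
#' eigenvalues above the mean eigenvalue. The classical eigenvalue > 1
#' cutoff (meaningful on correlation-scaled data) is available via
#' `kaiser = "unit"`.
#'
#' @param x numeric matrix, samples x features (no missing values).
#' @param labels class label per sample; at least two samples per class.
#' @param kaiser `"mean"` (Kaiser-Guttman, default) or `"unit"`.
#' @param min_components floor on the number of retained components
#'   (default 2).
#' @return a `PCDFAModel`: centering vector, PCA `loadings` and
#'   `eigenvalues`, `n_components`, discriminant projection `W`, class
#'   `centroids`, per-sample `df_scores` (DF1, DF2, ...), `labels`.
#' @export
fit_pcdfa <- function(x, labels, kaiser = c("mean", "unit"),
                      min_components = 2) {
  kaiser <- match.arg(kaiser)
  x <- as.matrix(x)
  labels <- factor(labels)
  if (any(is.na(x))) stop("PC-DFA input must not contain missing values")
  if (nrow(x) != length(labels)) stop("one label per row required")
  if (nrow(x) <= nlevels(labels))
    stop("discriminant analysis undefined: n_samples <= n_groups")
  if (any(table(labels) < 2)) stop("every class needs >= 2 samples")
  if (ncol(x) < 2) stop("need at least two features")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- svd(xc)
  ev <- sv$d^2 / (nrow(x) - 1)          # PC variances
  pos <- sum(ev > max(ev) * 1e-12)
  thr <- if (kaiser == "mean") mean(ev[seq_len(pos)]) else 1
  ncomp <- sum(ev[seq_len(pos)] > thr)
  ncomp <- max(ncomp, min_components)
  ncomp <- min(ncomp, pos)
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  scores <- xc %*% loadings
  lda <- fisher_lda(scores, labels)
  structure(list(center = center, loadings = loadings, eigenvalues = ev,
                 n_components = ncomp, W = lda$W,
                 centroids = lda$centroids,
                 df_scores = lda$scores, labels = labels),
            class = "PCDFAModel")
}

#' Classify samples with a fitted PC-DFA model
#'
#' Projects new samples through the training centering, PCA loadings and
#' discriminant axes, then assigns each to the nearest class centroid in
#' discriminant space (Euclidean distance).
#'
#' @param object a `PCDFAModel`.
#' @param newdata numeric matrix, samples x features (same feature order
#'   as the training matrix).
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.PCDFAModel <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  xc <- sweep(newdata, 2, object$center)
  df <- xc %*% object$loadings %*% object$W
  cls <- rownames(object$centroids)
  apply(df, 1, function(v) {
    d2 <- rowSums(sweep(object$centroids, 2, v)^2)
    cls[which.min(d2)]
  })
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement `p_e` from the marginal products. Perfect agreement with
#' degenerate marginals (`p_e` = 1, `p_o` = 1) returns 1.
#'
#' @param confusion square non-negative matrix, rows = truth,
#'   columns = prediction.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  n <- sum(confusion)
  if (n <= 0) stop("confusion matrix must have positive total")
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (pe >= 1) return(if (po >= 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Monte Carlo cross-validation of the PC-DFA pipeline
#'
#' Repeated stratified random splitting: per iteration the whole pipeline
#' (centering, PCA, Kaiser retention, discriminant axes) is refit on the
#' training fold only, test samples are projected and classified by
#' nearest centroid, and the confusion counts are pooled. Accuracy is
#' reported per iteration and as the mean; Cohen's kappa is computed on
#' the pooled confusion matrix. Reproducible for a fixed seed.
#'
#' @param x numeric matrix, samples x features.
#' @param labels class label per sample.
#' @param n_iter number of random splits (default 1000).
#' @param test_fraction fraction of each class held out (default 0.3);
#'   every class must keep at least two training samples.
#' @param seed integer seed.
#' @param ... forwarded to [fit_pcdfa()].
#' @return an `MCCVResult` list: `n_iter`, `test_fraction`, `accuracy`
#'   (per iteration), `mean_accuracy`, `kappa`, `confusion` (pooled).
#' @export
mccv <- function(x, labels, n_iter = 1000, test_fraction = 0.3,
                 seed = 1L, ...) {
  x <- as.matrix(x)
  labels <- factor(labels)
  cls <- levels(labels)
  idx_by_class <- split(seq_along(labels), labels)
  n_test <- vapply(idx_by_class, function(ix)
    max(1L, as.integer(floor(length(ix) * test_fraction))), integer(1))
  if (any(lengths(idx_by_class) - n_test < 2))
    stop("test_fraction leaves fewer than two training samples in a class")
  set.seed(seed)
  conf <- matrix(0L, length(cls), length(cls), dimnames = list(cls, cls))
  acc <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    test_idx <- unlist(lapply(seq_along(idx_by_class), function(ci)
      sample(idx_by_class[[ci]], n_test[ci])))
    train_idx <- setdiff(seq_along(labels), test_idx)
    model <- fit_pcdfa(x[train_idx, , drop = FALSE], labels[train_idx], ...)
    pred <- predict(model, x[test_idx, , drop = FALSE])
    truth <- as.character(labels[test_idx])
    acc[it] <- mean(pred == truth)
    for (j in seq_along(test_idx))
      conf[truth[j], pred[j]] <- conf[truth[j], pred[j]] + 1L
  }
  structure(list(n_iter = n_iter, test_fraction = test_fraction,
                 accuracy = acc, mean_accuracy = mean(acc),
                 kappa = cohens_kappa(conf), confusion = conf),
            class = "MCCVResult")
}

#' @export
print.MCCVResult <- function(x, ...) {
  cat("Monte Carlo cross-validation: ", x$n_iter, " iterations, ",
      round(100 * x$test_fraction), "% held out\n", sep = "")
  cat("  mean accuracy: ", round(x$mean_accuracy, 3),
      "   Cohen's kappa: ", round(x$kappa, 3), "\n", sep = "")
  invisible(x)
}
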