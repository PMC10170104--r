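# Small in-code fixtures used across the suite.

make_samples <- function(groups, n_qc = 0, column = "RP_PHENYL_HEXYL",
                         polarity = "POS") {
  ids <- c(unlist(lapply(names(groups), function(g)
    paste0(g, "_", seq_len(groups[[g]])))),
    if (n_qc) paste0("QC_", seq_len(n_qc)))
  grp <- c(rep(names(groups), unlist(groups)), rep("QC", n_qc))
  data.frame(sample_id = ids, group = grp,
             sample_type = ifelse(grp == "QC", "QC", "STUDY"),
             injection_order = seq_along(ids),
             column = column, polarity = polarity,
             stringsAsFactors = FALSE)
}

make_tiny_table <- function(areas, groups = c(I = 2, III = 2), n_qc = 0,
                            mz = NULL, rt = NULL, ...) {
  areas <- as.matrix(areas)
  nf <- nrow(areas)
  feats <- data.frame(feature_id = sprintf("F%02d", seq_len(nf)),
                      mz = if (is.null(mz)) 100 + seq_len(nf) else mz,
                      rt = if (is.null(rt)) 10 * seq_len(nf) else rt,
                      annotation = rep(NA_character_, nf),
                      stringsAsFactors = FALSE)
  feature_table(areas, feats, make_samples(groups, n_qc, ...))
}

# Table whose areas follow a known multiplicative linear drift, with QC
# injections spread evenly through the sequence. The generating curve is
# rescaled to median 1 over the QC injections, matching the correction's
# normalization convention, so `pre_drift` is an exact oracle for the
# corrected areas when cv = 0.
make_drifted_table <- function(n_feat = 10, n_per_group = 3, n_qc = 6,
                               base = 1000, drift_slope = 0.01, cv = 0,
                               seed = 1) {
  set.seed(seed)
  groups <- c(I = n_per_group, III = n_per_group)
  samples <- make_samples(groups, n_qc = n_qc)
  n <- nrow(samples)
  qc_pos <- unique(round(seq(1, n, length.out = n_qc)))
  study_pos <- setdiff(seq_len(n), qc_pos)
  ord <- integer(n)
  ord[samples$sample_type == "QC"] <- qc_pos[seq_len(sum(
    samples$sample_type == "QC"))]
  ord[samples$sample_type == "STUDY"] <- study_pos
  samples$injection_order <- ord
  base_f <- base * exp(stats::rnorm(n_feat, 0, 0.5))
  d <- 1 + drift_slope * (ord - 1)
  d <- d / stats::median(d[samples$sample_type == "QC"])
  areas <- outer(base_f, d)
  if (cv > 0) {
    sdl <- sqrt(log(1 + cv^2))
    areas <- areas * matrix(exp(stats::rnorm(n_feat * n, -sdl^2 / 2, sdl)),
                            n_feat, n)
  }
  feats <- data.frame(feature_id = sprintf("F%02d", seq_len(n_feat)),
                      mz = 100 + seq_len(n_feat), rt = 10 * seq_len(n_feat),
                      annotation = NA_character_, stringsAsFactors = FALSE)
  tab <- feature_table(areas, feats, samples)
  list(table = tab, pre_drift = outer(base_f, rep(1, n)), drift = d)
}
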