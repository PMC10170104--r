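GROUP_LEVELS <- c("I", "II", "III", "IV", "III_B", "IV_B", "QC")
STUDY_GROUPS <- c("I", "II", "III", "IV", "III_B", "IV_B")
COLUMN_LEVELS <- c("RP_PHENYL_HEXYL", "HILIC")
POLARITY_LEVELS <- c("POS", "NEG")

#' Construct a feature table
#'
#' A `FeatureTable` bundles a non-negative peak-area matrix (features in rows,
#' samples in columns, `NA` meaning "not detected") with feature metadata
#' (m/z in Th, retention time in seconds, optional isotope/adduct annotation)
#' and sample metadata (extraction group, sample type, injection order and
#' the analytical run, i.e. chromatographic column x ionization polarity).
#' It is the object every pipeline stage consumes and returns.
#'
#' @param areas numeric matrix, features x samples; `NA` encodes a missing
#'   (undetected) area. Zero is a legitimate measured area and is kept
#'   distinct from missing.
#' @param features data.frame with columns `feature_id`, `mz`, `rt` and
#'   optionally `annotation`.
#' @param samples data.frame with columns `sample_id`, `group`,
#'   `sample_type`, `injection_order`, `column`, `polarity`.
#' @return an object of class `FeatureTable`.
#' @export
feature_table <- function(areas, features, samples) {
  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(features$annotation)) features$annotation <- NA_character_
  ft <- structure(list(areas = areas, features = features, samples = samples),
                  class = "FeatureTable")
  validate_feature_table(ft)
  dimnames(ft$areas) <- list(features$feature_id, samples$sample_id)
  ft
}

#' Validate the structural invariants of a feature table
#'
#' Checks dimension agreement between the area matrix and the metadata,
#' uniqueness of feature and sample ids, non-negativity of areas, closed
#' group/column/polarity vocabularies, positive m/z, non-negative retention
#' times, unique injection orders within a run, and the coupling between the
#' QC group label and the QC sample type.
#'
#' @param ft a `FeatureTable`.
#' @return `ft`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_feature_table <- function(ft) {
  areas <- ft$areas; feat <- ft$features; samp <- ft$samples
  req_f <- c("feature_id", "mz", "rt")
  req_s <- c("sample_id", "group", "sample_type", "injection_order",
             "column", "polarity")
  miss <- setdiff(req_f, names(feat))
  if (length(miss)) stop("feature metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(req_s, names(samp))
  if (length(miss)) stop("sample metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(areas) != nrow(feat))
    stop("area matrix has ", nrow(areas), " rows but feature metadata has ",
         nrow(feat), " entries")
  if (ncol(areas) != nrow(samp))
    stop("area matrix has ", ncol(areas), " columns but sample metadata has ",
         nrow(samp), " entries")
  dup <- feat$feature_id[duplicated(feat$feature_id)]
  if (length(dup)) stop("duplicated feature_id: ",
                        paste(unique(dup), collapse = ", "))
  dup <- samp$sample_id[duplicated(samp$sample_id)]
  if (length(dup)) stop("duplicated sample_id: ",
                        paste(unique(dup), collapse = ", "))
  if (nrow(feat)) {
    if (any(!is.finite(feat$mz) | feat$mz <= 0))
      stop("non-positive or non-numeric mz for feature(s): ",
           paste(feat$feature_id[!is.finite(feat$mz) | feat$mz <= 0],
                 collapse = ", "))
    if (any(!is.finite(feat$rt) | feat$rt < 0))
      stop("negative retention time for feature(s): ",
           paste(feat$feature_id[!is.finite(feat$rt) | feat$rt < 0],
                 collapse = ", "))
  }
  bad <- !(samp$group %in% GROUP_LEVELS)
  if (any(bad)) stop("unknown group label for sample(s) ",
                     paste(samp$sample_id[bad], collapse = ", "), ": ",
                     paste(unique(samp$group[bad]), collapse = ", "))
  bad <- !(samp$sample_type %in% c("STUDY", "QC"))
  if (any(bad)) stop("unknown sample_type for sample(s): ",
                     paste(samp$sample_id[bad], collapse = ", "))
  bad <- !(samp$column %in% COLUMN_LEVELS)
  if (any(bad)) stop("unknown column for sample(s): ",
                     paste(samp$sample_id[bad], collapse = ", "))
  bad <- !(samp$polarity %in% POLARITY_LEVELS)
  if (any(bad)) stop("unknown polarity for sample(s): ",
                     paste(samp$sample_id[bad], collapse = ", "))
  if (any((samp$group == "QC") != (samp$sample_type == "QC")))
    stop("group 'QC' and sample_type 'QC' must coincide; offending sample(s): ",
         paste(samp$sample_id[(samp$group == "QC") !=
                                (samp$sample_type == "QC")], collapse = ", "))
  io <- samp$injection_order
  if (any(!is.finite(io) | io <= 0 | io != round(io)))
    stop("injection_order must be a positive integer for every sample")
  for (run in split(samp, paste(samp$column, samp$polarity))) {
    if (anyDuplicated(run$injection_order))
      stop("duplicated injection_order within run ",
           run$column[1], "/", run$polarity[1])
  }
  if (nrow(areas) && ncol(areas)) {
    neg <- which(!is.na(areas) & areas < 0, arr.ind = TRUE)
    if (nrow(neg))
      stop("negative area at feature ", feat$feature_id[neg[1, 1]],
           ", sample ", samp$sample_id[neg[1, 2]])
  }
  invisible(ft)
}

#' @export
print.FeatureTable <- function(x, ...) {
  ns <- table(factor(x$samples$group, levels = GROUP_LEVELS))
  cat("FeatureTable: ", nrow(x$features), " features x ",
      nrow(x$samples), " samples\n", sep = "")
  cat("  run: ", paste(unique(paste(x$samples$column, x$samples$polarity,
                                    sep = "/")), collapse = ", "), "\n",
      sep = "")
  cat("  samples per group: ",
      paste(names(ns)[ns > 0], ns[ns > 0], sep = "=", collapse = " "), "\n",
      sep = "")
  cat("  missing areas: ", sum(is.na(x$areas)), " (",
      round(100 * mean(is.na(x$areas)), 1), "%)\n", sep = "")
  invisible(x)
}

#' Read a feature table from its two CSV files
#'
#' The areas file carries one row per feature with columns `feature_id`,
#' `mz`, `rt`, `annotation` followed by one column per sample; empty cells
#' are parsed as missing areas (`NA`), never as zero. The samples file
#' carries the sample metadata. Both use comma separator, decimal point and
#' a mandatory header row.
#'
#' @param areas_path path to the areas CSV.
#' @param samples_path path to the sample-metadata CSV.
#' @return a validated `FeatureTable`.
#' @export
read_feature_table <- function(areas_path, samples_path) {
  if (!file.exists(areas_path)) stop("areas file not found: ", areas_path)
  if (!file.exists(samples_path)) stop("samples file not found: ",
                                       samples_path)
  ar <- utils::read.csv(areas_path, check.names = FALSE,
                        stringsAsFactors = FALSE,
                        colClasses = c(feature_id = "character"))
  sm <- utils::read.csv(samples_path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character"))
  meta_cols <- c("feature_id", "mz", "rt", "annotation")
  miss <- setdiff(meta_cols, names(ar))
  if (length(miss)) stop("areas file lacks column(s): ",
                         paste(miss, collapse = ", "))
  sample_cols <- setdiff(names(ar), meta_cols)
  if (!setequal(sample_cols, sm$sample_id))
    stop("sample columns of the areas file do not match the sample ",
         "metadata; only in areas: ",
         paste(setdiff(sample_cols, sm$sample_id), collapse = ", "),
         "; only in metadata: ",
         paste(setdiff(sm$sample_id, sample_cols), collapse = ", "))
  areas <- as.matrix(ar[, sm$sample_id, drop = FALSE])
  storage.mode(areas) <- "double"
  feat <- ar[, meta_cols]
  feat$annotation[!is.na(feat$annotation) & feat$annotation == ""] <-
    NA_character_
  feature_table(areas, feat, sm)
}

#' Write a feature table to its two CSV files
#'
#' Inverse of [read_feature_table()]: missing areas are serialized as empty
#' fields so that a round trip restores the table exactly.
#'
#' @param table a `FeatureTable`.
#' @param areas_path,samples_path output paths.
#' @return invisibly, the two paths.
#' @export
write_feature_table <- function(table, areas_path, samples_path) {
  validate_feature_table(table)
  # serialize doubles at full precision so the round trip is bitwise
  full <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  df <- data.frame(feature_id = table$features$feature_id,
                   mz = full(table$features$mz),
                   rt = full(table$features$rt),
                   annotation = table$features$annotation,
                   stringsAsFactors = FALSE, check.names = FALSE)
  ar <- matrix(full(table$areas), nrow = nrow(table$areas),
               ncol = ncol(table$areas),
               dimnames = list(NULL, table$samples$sample_id))
  df <- cbind(df, as.data.frame(ar, check.names = FALSE,
                                stringsAsFactors = FALSE))
  utils::write.csv(df, areas_path, row.names = FALSE, na = "")
  utils::write.csv(table$samples, samples_path, row.names = FALSE, na = "")
  invisible(c(areas_path, samples_path))
}

#' Read a compound registry
#'
#' The registry catalogues the targeted evaluation panel: molecules of
#' interest (MoInt) and spiked internal standards (IS), one record per
#' compound and ionization polarity, with m/z, per-column retention times
#' and detection flags, HMDB compound subclass, spike-solution membership
#' for internal standards, and database identifiers where known.
#'
#' @param path path to a registry CSV with columns `name`, `polarity`,
#'   `mz`, `rt_rp`, `rt_hilic`, `detected_rp`, `detected_hilic`,
#'   `compound_subclass`, `role` (`MOINT` or `IS`), `spike_group`,
#'   `hmdb_id`, `kegg_id`.
#' @return a data.frame of class `CompoundRegistry`.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("name", "polarity", "mz", "rt_rp", "rt_hilic", "detected_rp",
           "detected_hilic", "compound_subclass", "role", "spike_group",
           "hmdb_id", "kegg_id")
  miss <- setdiff(req, names(reg))
  if (length(miss)) stop("registry lacks required column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(reg$mz)))
    stop("non-numeric m/z for compound(s): ",
         paste(reg$name[!is.finite(reg$mz)], collapse = ", "))
  if (any(!reg$polarity %in% POLARITY_LEVELS))
    stop("unknown polarity in registry")
  if (any(!reg$role %in% c("MOINT", "IS")))
    stop("role must be MOINT or IS")
  reg$detected_rp <- as.logical(reg$detected_rp)
  reg$detected_hilic <- as.logical(reg$detected_hilic)
  for (col in c("hmdb_id", "kegg_id", "spike_group"))
    reg[[col]][!is.na(reg[[col]]) & reg[[col]] == ""] <- NA
  bad <- (reg$detected_rp & !is.finite(reg$rt_rp)) |
    (reg$detected_hilic & !is.finite(reg$rt_hilic))
  if (any(bad))
    stop("detected compound(s) without a retention time: ",
         paste(reg$name[bad], collapse = ", "))
  if (anyDuplicated(reg[, c("name", "polarity")]))
    stop("duplicated (name, polarity) record in registry")
  class(reg) <- c("CompoundRegistry", "data.frame")
  reg
}

#' Paths of the bundled registry fixtures
#'
#' `moint_registry()` returns the molecules-of-interest panel (35 unique
#' compounds; 34 positive-mode and 16 negative-mode records).
#' `is_registry()` returns the nine spiked internal standards; the file is
#' labelled synthetic because the printed source reports only compound
#' names, spike solutions and detection behaviour, so m/z and retention
#' times in this fixture are reconstructed values.
#'
#' @return a file path suitable for [read_registry()].
#' @export
moint_registry_path <- function() {
  system.file("extdata", "moint_registry.csv", package = "metaboextract",
              mustWork = TRUE)
}

#' @rdname moint_registry_path
#' @export
is_registry_path <- function() {
  system.file("extdata", "is_registry_synthetic.csv",
              package = "metaboextract", mustWork = TRUE)
}

#' Read a pathway library fixture
#'
#' A pathway library is a JSON file mapping pathway names to an object with
#' `members` (compound identifiers) and `edges` (pairs of member ids forming
#' an undirected, unweighted reaction graph). Graphs may be disconnected;
#' every edge endpoint must be a member.
#'
#' @param path path to the JSON file.
#' @return a named list of pathway definitions, each a list with elements
#'   `name`, `members` (character) and `edges` (2-column character matrix).
#' @export
read_pathway_library <- function(path) {
  if (!file.exists(path)) stop("pathway library not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(raw)) stop("pathway library is empty")
  out <- lapply(names(raw), function(nm) {
    p <- raw[[nm]]
    members <- unlist(p$members, use.names = FALSE)
    edges <- if (length(p$edges)) {
      do.call(rbind, lapply(p$edges, function(e) unlist(e, use.names = FALSE)))
    } else {
      matrix(character(), ncol = 2)
    }
    if (nrow(edges) && !all(edges %in% members))
      stop("pathway '", nm, "' has an edge endpoint outside its member set")
    list(name = nm, members = members, edges = edges)
  })
  names(out) <- names(raw)
  out
}

#' @rdname read_pathway_library
#' @export
pathway_library_path <- function() {
  system.file("extdata", "pathways_synthetic.json", package = "metaboextract",
              mustWork = TRUE)
}
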