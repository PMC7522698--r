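#' Labeled metabolomic feature table
#'
#' The universal data container of the pipeline: a samples x features matrix
#' of peak intensities with a binary class label per sample. Missing peaks
#' (not detected in a sample) are `NA`; all observed intensities must be
#' non-negative.
#'
#' @param intensities numeric matrix, rows = samples, columns = features.
#'   `NA` marks a missing (undetected) peak.
#' @param labels character or factor of per-sample labels; one of `"EC"`,
#'   `"control"`, `"unknown"`.
#' @param sample_ids unique sample identifiers; defaults to rownames or
#'   `S1..Sn`.
#' @param feature_ids unique feature identifiers; defaults to colnames or
#'   `M1..Mp`.
#'
#' @return An object of class `feature_table`: a list with elements
#'   `intensities` (matrix with dimnames), `labels` (character vector).
#' @export
feature_table <- function(intensities, labels,
                          sample_ids = NULL, feature_ids = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(intensities)
  p <- ncol(intensities)
  sample_ids <- sample_ids %||% rownames(intensities) %||% paste0("S", seq_len(n))
  feature_ids <- feature_ids %||% colnames(intensities) %||% paste0("M", seq_len(p))
  check_that(length(sample_ids) == n, "sample_ids", "length must equal row count")
  check_that(length(feature_ids) == p, "feature_ids", "length must equal column count")
  check_that(!anyDuplicated(sample_ids), "sample_ids", "must be unique")
  check_that(!anyDuplicated(feature_ids), "feature_ids", "must be unique")
  labels <- as.character(labels)
  check_that(length(labels) == n, "labels", "one label per sample required")
  check_that(all(labels %in% c("EC", "control", "unknown")), "labels",
             "values must be 'EC', 'control' or 'unknown'")
  obs <- intensities[!is.na(intensities)]
  check_that(all(obs >= 0), "intensities", "observed intensities must be >= 0")
  dimnames(intensities) <- list(as.character(sample_ids), as.character(feature_ids))
  structure(list(intensities = intensities, labels = labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("EC", "control", "unknown")))
  cat(sprintf("feature_table: %d samples x %d features\n",
              nrow(x$intensities), ncol(x$intensities)))
  cat(sprintf("  labels: EC=%d control=%d unknown=%d\n",
              tab[["EC"]], tab[["control"]], tab[["unknown"]]))
  cat(sprintf("  missing cells: %.1f%%\n",
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

sample_ids <- function(table) rownames(table$intensities)
feature_ids <- function(table) colnames(table$intensities)

# Internal subsetting. Skips re-validation: the inputs are already valid
# tables, and preprocessed (scaled) tables legitimately hold negative
# values that the public constructor's raw-intensity check would reject.
subset_samples <- function(table, idx) {
  out <- table
  out$intensities <- table$intensities[idx, , drop = FALSE]
  out$labels <- table$labels[idx]
  out
}

subset_features <- function(table, keep) {
  out <- table
  out$intensities <- table$intensities[, keep, drop = FALSE]
  out
}

#' Write a labeled feature table to CSV
#'
#' Layout: first column `sample_id`, second `label`, remaining columns one
#' per feature; missing intensities become empty cells. UTF-8 with header.
#'
#' @param table a [feature_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(sample_id = sample_ids(table),
                   label = table$labels,
                   table$intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a labeled feature table from CSV
#'
#' Expects the layout written by [write_feature_table()]. A missing `label`
#' column is allowed for screening tables and filled with `"unknown"`.
#'
#' @param path CSV file path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_that("sample_id" %in% names(df), "path", "CSV must have a sample_id column")
  ids <- as.character(df$sample_id)
  labels <- if ("label" %in% names(df)) as.character(df$label) else rep("unknown", nrow(df))
  labels[is.na(labels) | labels == ""] <- "unknown"
  feat_cols <- setdiff(names(df), c("sample_id", "label"))
  mat <- as.matrix(df[, feat_cols, drop = FALSE])
  storage.mode(mat) <- "double"
  feature_table(mat, labels, sample_ids = ids, feature_ids = feat_cols)
}
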