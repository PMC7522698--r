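#' Presence-based feature retention
#'
#' Keeps the peaks consistently observed in at least `presence_threshold`
#' of samples (non-missing fraction >= threshold; "at least" is inclusive)
#' and additionally drops zero-variance peaks, whose constant observed
#' values carry no class information and break downstream standardization.
#' Surviving column order is preserved. Filtering never looks at labels.
#'
#' @param table a [feature_table()].
#' @param presence_threshold retention threshold in `(0, 1]`; default 0.75.
#' @return list with elements `table` (filtered [feature_table()]) and
#'   `report` (a `filter_report`: counts, per-feature drop reasons, and the
#'   threshold used).
#' @export
filter_features <- function(table, presence_threshold = 0.75) {
  stopifnot(inherits(table, "feature_table"))
  check_that(nrow(table$intensities) > 0 && ncol(table$intensities) > 0,
             "table", "must contain at least one sample and one feature")
  check_that(is.numeric(presence_threshold) && presence_threshold > 0 &&
               presence_threshold <= 1,
             "presence_threshold", "must lie in (0, 1]")
  x <- table$intensities
  presence <- colMeans(!is.na(x))
  obs_var <- apply(x, 2, function(col) {
    v <- col[!is.na(col)]
    if (length(v) < 2) 0 else stats::var(v)
  })
  low_presence <- presence < presence_threshold
  zero_var <- !low_presence & obs_var == 0
  keep <- !low_presence & !zero_var

  dropped <- data.frame(
    feature_id = colnames(x)[!keep],
    reason = ifelse(low_presence[!keep], "low_presence", "zero_variance"),
    presence = unname(presence[!keep]),
    stringsAsFactors = FALSE
  )
  report <- structure(list(n_features_in = ncol(x),
                           n_features_kept = sum(keep),
                           dropped = dropped,
                           presence_threshold = presence_threshold),
                      class = "filter_report")
  list(table = subset_features(table, which(keep)), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d -> %d features (presence >= %.0f%%)\n",
              x$n_features_in, x$n_features_kept,
              100 * x$presence_threshold))
  if (nrow(x$dropped)) {
    cat(sprintf("  dropped: %d low-presence, %d zero-variance\n",
                sum(x$dropped$reason == "low_presence"),
                sum(x$dropped$reason == "zero_variance")))
  }
  invisible(x)
}

#' Serialize a filter report / keep-list
#'
#' @param report a `filter_report` from [filter_features()].
#' @param path destination: `.json` for the full report.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Export the surviving feature list as a one-column text file
#' @param table a filtered [feature_table()].
#' @param path destination text file, one feature id per line.
#' @return `path`, invisibly.
#' @export
write_keep_list <- function(table, path) {
  writeLines(feature_ids(table), path)
  invisible(path)
}

# Fit imputation fill values on (training) data. half_min: half the
# feature's minimum observed intensity, the conventional stand-in for
# below-detection-limit peaks; feature_median: median of observed values.
fit_impute <- function(table, strategy = c("half_min", "feature_median")) {
  strategy <- match.arg(strategy)
  x <- table$intensities
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0)) {
    stop("features with no observed values (should have been filtered): ",
         paste(colnames(x)[n_obs == 0], collapse = ", "), call. = FALSE)
  }
  fill <- apply(x, 2, function(col) {
    v <- col[!is.na(col)]
    if (strategy == "half_min") min(v) / 2 else stats::median(v)
  })
  list(strategy = strategy, fill = fill)
}

apply_impute <- function(table, params) {
  x <- table$intensities
  common <- intersect(colnames(x), names(params$fill))
  for (j in common) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- params$fill[[j]]
  }
  if (anyNA(x)) {
    stop("missing values remain after imputation (features unseen at fit time)",
         call. = FALSE)
  }
  feature_table(x, table$labels)
}

#' Impute missing intensities
#'
#' Replaces missing cells per feature, by default with half the feature's
#' minimum observed value (`half_min`, the usual convention for peaks below
#' the detection limit) or with the feature median (`feature_median`).
#'
#' @param table a filtered [feature_table()].
#' @param strategy `"half_min"` (default) or `"feature_median"`.
#' @return A complete [feature_table()] (no missing values).
#' @export
impute_missing <- function(table, strategy = c("half_min", "feature_median")) {
  stopifnot(inherits(table, "feature_table"))
  if (!anyNA(table$intensities)) return(table)
  apply_impute(table, fit_impute(table, strategy))
}

#' Log-transform and standardize features
#'
#' Natural-log transform followed by per-feature standardization to mean 0,
#' sd 1. When `params` (from a previous fit) is supplied, its means and
#' sds are applied unchanged — the screening-cohort path, which must reuse
#' the training parameters rather than refit them.
#'
#' @param table a complete [feature_table()] (no missing values).
#' @param params optional `scaling_params` from an earlier call.
#' @param log_transform apply `log()` before standardizing (default TRUE).
#' @return list with `table` (transformed) and `params`
#'   (`scaling_params`: per-feature `mu`, `sigma`, and `log_transform`).
#' @export
scale_features <- function(table, params = NULL, log_transform = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$intensities
  if (anyNA(x)) stop("impute missing values before scaling", call. = FALSE)
  if (!is.null(params)) log_transform <- params$log_transform
  if (log_transform) {
    bad <- which(x <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-positive intensity at sample '%s', feature '%s': cannot log-transform",
                   rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]),
           call. = FALSE)
    }
    x <- log(x)
  }
  if (is.null(params)) {
    mu <- colMeans(x)
    sigma <- apply(x, 2, stats::sd)
    if (any(sigma == 0)) {
      stop("zero-variance feature(s) cannot be standardized: ",
           paste(colnames(x)[sigma == 0], collapse = ", "),
           " (apply filter_features first)", call. = FALSE)
    }
    params <- structure(list(mu = mu, sigma = sigma,
                             log_transform = log_transform),
                        class = "scaling_params")
  } else {
    stopifnot(inherits(params, "scaling_params"))
    missing_feat <- setdiff(colnames(x), names(params$mu))
    if (length(missing_feat)) {
      stop("features without fitted scaling parameters: ",
           paste(missing_feat, collapse = ", "), call. = FALSE)
    }
  }
  x <- sweep(x, 2, params$mu[colnames(x)], "-")
  x <- sweep(x, 2, params$sigma[colnames(x)], "/")
  out <- table
  out$intensities <- x
  # scaled values may legitimately be negative; bypass the >= 0 check
  list(table = out, params = params)
}

# Full preprocessing fit: imputation fills + scaling params on a training
# table that has already been presence-filtered.
fit_preprocess <- function(table, impute_strategy = "half_min",
                           log_transform = TRUE) {
  imp <- fit_impute(table, impute_strategy)
  complete <- apply_impute(table, imp)
  sc <- scale_features(complete, log_transform = log_transform)
  list(impute = imp, scaling = sc$params, feature_ids = feature_ids(table))
}

# Apply a fitted preprocessing state (keep-list alignment, imputation with
# training fills, scaling with training params) to any table.
apply_preprocess <- function(table, prep) {
  missing_feat <- setdiff(prep$feature_ids, feature_ids(table))
  if (length(missing_feat)) {
    stop("table lacks required features: ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  }
  aligned <- subset_features(table, prep$feature_ids)
  complete <- apply_impute(aligned, prep$impute)
  scale_features(complete, params = prep$scaling)$table
}
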