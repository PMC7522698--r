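#' Confusion counts from predicted and true classes
#'
#' @param predicted,truth character vectors of `"EC"` / `"control"` calls
#'   (truth must not contain `"unknown"`).
#' @return A `confusion_counts` list with `tp`, `fp`, `fn`, `tn`
#'   (EC = positive class).
#' @export
confusion_counts <- function(predicted, truth) {
  check_that(length(predicted) == length(truth), "predicted",
             "must match length of truth")
  check_that(all(truth %in% c("EC", "control")), "truth",
             "labels must be 'EC' or 'control'")
  check_that(all(predicted %in% c("EC", "control")), "predicted",
             "calls must be 'EC' or 'control'")
  structure(list(tp = sum(predicted == "EC" & truth == "EC"),
                 fp = sum(predicted == "EC" & truth == "control"),
                 fn = sum(predicted == "control" & truth == "EC"),
                 tn = sum(predicted == "control" & truth == "control")),
            class = "confusion_counts")
}

ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_
prop_se <- function(p, n) if (!is.na(p) && n > 0) sqrt(p * (1 - p) / n) else NA_real_

#' Diagnostic screening metrics from a confusion matrix
#'
#' Computes the seven standard screening-test indices, each with a binomial
#' standard error on its own denominator:
#' sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)`, accuracy `(tp+tn)/total`, LR+ `sens/(1-spec)`,
#' LR- `(1-sens)/spec`, plus prevalence `(tp+fn)/total`. A metric whose
#' denominator is zero is undefined and reported as `NA` (rendered "ND" in
#' tables), never coerced to 0 or 1; in particular LR+ is undefined at
#' specificity 1.
#'
#' @param tp a [confusion_counts()], or the true-positive count when the
#'   four counts are given separately.
#' @param fp,fn,tn the remaining counts when not using a
#'   `confusion_counts`.
#' @return A `screening_metrics` list: the counts, all metrics as
#'   fractions, and `se` (named standard errors).
#' @export
#' @examples
#' m <- screening_metrics(tp = 16, fp = 2, fn = 0, tn = 1412)
#' round(100 * m$ppv, 1)   # 88.9
#' m$lr_pos                # 707
screening_metrics <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  counts <- if (inherits(tp, "confusion_counts")) tp else
    structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
              class = "confusion_counts")
  with(counts, {
    check_that(all(c(tp, fp, fn, tn) >= 0) &&
                 all(c(tp, fp, fn, tn) == floor(c(tp, fp, fn, tn))),
               "counts", "must be non-negative integers")
    total <- tp + fp + fn + tn
    check_that(total > 0, "counts", "confusion matrix is empty")
    sens <- ratio_or_na(tp, tp + fn)
    spec <- ratio_or_na(tn, tn + fp)
    ppv <- ratio_or_na(tp, tp + fp)
    npv <- ratio_or_na(tn, tn + fn)
    acc <- (tp + tn) / total
    lr_pos <- if (is.na(spec)) NA_real_ else ratio_or_na(sens, 1 - spec)
    lr_neg <- if (is.na(spec) || spec == 0) NA_real_ else (1 - sens) / spec
    structure(list(
      counts = list(tp = tp, fp = fp, fn = fn, tn = tn),
      total = total,
      sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
      accuracy = acc, lr_pos = lr_pos, lr_neg = lr_neg,
      prevalence = (tp + fn) / total,
      se = c(sensitivity = prop_se(sens, tp + fn),
             specificity = prop_se(spec, tn + fp),
             ppv = prop_se(ppv, tp + fp),
             npv = prop_se(npv, tn + fn),
             accuracy = prop_se(acc, total))),
      class = "screening_metrics")
  })
}

fmt_pct <- function(p, se = NULL) {
  if (is.na(p)) return("ND")
  if (is.null(se) || is.na(se)) sprintf("%.1f", 100 * p)
  else sprintf("%.1f (%.1f)", 100 * p, 100 * se)
}

#' @export
print.screening_metrics <- function(x, ...) {
  cat("screening_metrics (EC = positive):\n")
  cat(sprintf("  counts: TP=%d FP=%d FN=%d TN=%d (n=%d, prevalence %.2f%%)\n",
              x$counts$tp, x$counts$fp, x$counts$fn, x$counts$tn,
              x$total, 100 * x$prevalence))
  cat(sprintf("  sensitivity %% (SE): %s\n", fmt_pct(x$sensitivity, x$se["sensitivity"])))
  cat(sprintf("  specificity %% (SE): %s\n", fmt_pct(x$specificity, x$se["specificity"])))
  cat(sprintf("  PPV %% (SE):         %s\n", fmt_pct(x$ppv, x$se["ppv"])))
  cat(sprintf("  NPV %% (SE):         %s\n", fmt_pct(x$npv, x$se["npv"])))
  cat(sprintf("  accuracy %% (SE):    %s\n", fmt_pct(x$accuracy, x$se["accuracy"])))
  cat(sprintf("  LR+: %s   LR-: %s\n",
              ifelse(is.na(x$lr_pos), "ND", sprintf("%.1f", x$lr_pos)),
              ifelse(is.na(x$lr_neg), "ND", sprintf("%.2f", x$lr_neg))))
  invisible(x)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Sweeps all decision thresholds of the rule `score > t` (via pROC),
#' reporting the full (FPR, TPR) curve, the trapezoidal AUC (identical to
#' the Mann-Whitney rank statistic), and the cutoff maximizing the Youden
#' index J = sensitivity + specificity - 1, with ties broken toward the
#' higher-specificity threshold.
#'
#' @param scores numeric per-sample scores; higher = more EC-like.
#' @param labels per-sample `"EC"` / `"control"` labels.
#' @return A `roc_analysis`: `thresholds`, `fpr`, `tpr`, `auc`,
#'   `youden_cutoff`, `youden_j`, and the underlying `pROC::roc` object
#'   (`roc`).
#' @export
roc_analysis <- function(scores, labels) {
  check_that(length(scores) == length(labels), "scores",
             "must match length of labels")
  check_that(all(c("EC", "control") %in% labels), "labels",
             "both classes must be present")
  r <- pROC::roc(response = factor(labels, levels = c("control", "EC")),
                 predictor = scores, levels = c("control", "EC"),
                 direction = "<", quiet = TRUE)
  co <- pROC::coords(r, "all", ret = c("threshold", "sensitivity",
                                       "specificity"), transpose = FALSE)
  j <- co$sensitivity + co$specificity - 1
  best <- which(j == max(j))
  best <- best[which.max(co$specificity[best])]  # tie -> higher specificity
  structure(list(thresholds = co$threshold,
                 fpr = 1 - co$specificity,
                 tpr = co$sensitivity,
                 auc = as.numeric(pROC::auc(r)),
                 youden_cutoff = co$threshold[best],
                 youden_j = j[best],
                 roc = r),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf("roc_analysis: AUC %.4f, Youden cutoff %.4g (J = %.3f)\n",
              x$auc, x$youden_cutoff, x$youden_j))
  invisible(x)
}

#' Export ROC curve points as CSV
#' @param roc a `roc_analysis`.
#' @param path destination CSV (`threshold,fpr,tpr`).
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(roc, path) {
  utils::write.csv(data.frame(threshold = roc$thresholds, fpr = roc$fpr,
                              tpr = roc$tpr), path, row.names = FALSE)
  invisible(path)
}

#' DeLong comparison of two correlated AUCs
#'
#' Nonparametric comparison of the areas under two ROC curves computed
#' from paired scores on the same samples, using placement-value
#' (structural-component) estimates of the AUC variances and covariance;
#' `z = (AUC_a - AUC_b) / sqrt(var_a + var_b - 2 cov)` with a two-sided
#' normal p-value.
#'
#' @param scores_a,scores_b paired numeric score vectors (same samples).
#' @param labels per-sample `"EC"` / `"control"` labels.
#' @return A `delong_comparison`: `auc_a`, `auc_b`, `variance_a`,
#'   `variance_b`, `covariance`, `z`, `p_value`. Degenerate variance gives
#'   `NA` z and p.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  check_that(length(scores_a) == length(labels) &&
               length(scores_b) == length(labels),
             "scores_a", "scores and labels must have equal length")
  resp <- factor(labels, levels = c("control", "EC"))
  ra <- pROC::roc(resp, scores_a, levels = c("control", "EC"),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(resp, scores_b, levels = c("control", "EC"),
                  direction = "<", quiet = TRUE)
  va <- pROC::var(ra, method = "delong")
  vb <- pROC::var(rb, method = "delong")
  cv <- pROC::cov(ra, rb, method = "delong")
  denom2 <- va + vb - 2 * cv
  if (!is.finite(denom2) || denom2 <= 0) {
    z <- NA_real_
    p <- if (isTRUE(all.equal(as.numeric(pROC::auc(ra)),
                              as.numeric(pROC::auc(rb))))) 1 else NA_real_
  } else {
    z <- (as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb))) / sqrt(denom2)
    p <- 2 * (1 - stats::pnorm(abs(z)))
  }
  structure(list(auc_a = as.numeric(pROC::auc(ra)),
                 auc_b = as.numeric(pROC::auc(rb)),
                 variance_a = va, variance_b = vb, covariance = cv,
                 z = z, p_value = p),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("delong_comparison: AUC %.4f vs %.4f, z = %s, p = %s\n",
              x$auc_a, x$auc_b,
              ifelse(is.na(x$z), "NA", sprintf("%.3f", x$z)),
              ifelse(is.na(x$p_value), "NA", format.pval(x$p_value))))
  invisible(x)
}

# Latent-space class-separation statistic: Euclidean distance between the
# class centroids of the PLS scores, standardized by the pooled
# within-class spread (root mean squared distance to the own-class
# centroid) -- a multivariate effect size in score space.
separation_distance <- function(scores, y01) {
  scores <- as.matrix(scores)
  mu1 <- colMeans(scores[y01 == 1, , drop = FALSE])
  mu0 <- colMeans(scores[y01 == 0, , drop = FALSE])
  centered <- scores
  centered[y01 == 1, ] <- sweep(scores[y01 == 1, , drop = FALSE], 2, mu1)
  centered[y01 == 0, ] <- sweep(scores[y01 == 0, , drop = FALSE], 2, mu0)
  pooled <- sqrt(sum(centered^2) / (nrow(scores) - 2))
  sqrt(sum((mu1 - mu0)^2)) / pooled
}

# One PLS fit on preprocessed data; returns R2Y and scores.
pls_fit_stats <- function(x, y01, ncomp) {
  fit <- mixOmics::pls(x, y01, ncomp = ncomp, mode = "regression")
  pred <- stats::predict(fit, x)$predict[, 1, ncomp]
  r2y <- 1 - sum((y01 - pred)^2) / sum((y01 - mean(y01))^2)
  list(fit = fit, r2y = r2y, scores = fit$variates$X)
}

#' PLS-DA validation by permutation test
#'
#' Fits a two-class partial-least-squares discriminant model (labels coded
#' 0/1, regression mode) and reports: `r2y`, the in-fit fraction of label
#' variance explained; `q2y`, its cross-validated counterpart
#' (1 - PRESS/TSS over stratified folds, preprocessing refit per fold);
#' and a permutation test of class separation. The test statistic is the
#' separation distance — the distance between the class centroids in the
#' latent score space scaled by the pooled within-class spread — and the
#' null is built by refitting on label-permuted data;
#' `p = (1 + #permuted >= observed) / (n_permutations + 1)`.
#'
#' @param table labeled [feature_table()] (missing values are imputed,
#'   intensities log-transformed and autoscaled internally).
#' @param n_components PLS components (default 5).
#' @param n_permutations size of the permutation null (default 1000).
#' @param seed integer seed.
#' @param q2_folds folds for the Q2Y cross-validation (default 7).
#' @param log_transform log the intensities before autoscaling.
#' @return A `permutation_validation`: `r2y`, `q2y`, `n_permutations`,
#'   `observed_statistic`, `permuted_statistics`, `p_value`.
#' @export
plsda_validate <- function(table, n_components = 5, n_permutations = 1000,
                           seed = 1L, q2_folds = 7, log_transform = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  y <- table$labels
  check_that(all(y %in% c("EC", "control")) &&
               length(unique(y)) == 2, "table",
             "two labeled classes (EC and control) required")
  n <- length(y)
  check_that(is_count(n_components) && n_components >= 1 &&
               n_components < min(n, ncol(table$intensities)),
             "n_components", "must be < min(samples, features)")
  y01 <- as.numeric(y == "EC")

  complete <- impute_missing(table)
  x <- scale_features(complete, log_transform = log_transform)$table$intensities

  obs <- pls_fit_stats(x, y01, n_components)
  stat_obs <- separation_distance(obs$scores, y01)

  # Q2Y: stratified CV, scaling refit inside each training fold
  folds <- make_cv_folds(y, k = min(q2_folds, min(table(y))), seed = seed)
  press <- 0
  for (f in seq_len(max(folds))) {
    hold <- which(folds == f)
    tr <- subset_samples(complete, -hold)
    te <- subset_samples(complete, hold)
    sc <- scale_features(tr, log_transform = log_transform)
    xtr <- sc$table$intensities
    xte <- scale_features(te, params = sc$params)$table$intensities
    fit <- mixOmics::pls(xtr, y01[-hold], ncomp = n_components,
                         mode = "regression")
    pred <- stats::predict(fit, xte)$predict[, 1, n_components]
    press <- press + sum((y01[hold] - pred)^2)
  }
  q2y <- 1 - press / sum((y01 - mean(y01))^2)

  perm_stats <- vapply(seq_len(n_permutations), function(b) {
    yb <- with_seed(substream_seed(seed, b), sample(y01))
    pb <- mixOmics::pls(x, yb, ncomp = n_components, mode = "regression")
    separation_distance(pb$variates$X, yb)
  }, numeric(1))

  structure(list(r2y = obs$r2y, q2y = q2y,
                 n_permutations = n_permutations,
                 observed_statistic = stat_obs,
                 permuted_statistics = perm_stats,
                 p_value = (1 + sum(perm_stats >= stat_obs)) /
                   (n_permutations + 1)),
            class = "permutation_validation")
}

#' @export
print.permutation_validation <- function(x, ...) {
  cat(sprintf("permutation_validation: R2Y = %.3f, Q2Y = %.3f\n",
              x$r2y, x$q2y))
  cat(sprintf("  separation distance %.3f vs %d permutations: p = %.4g\n",
              x$observed_statistic, x$n_permutations, x$p_value))
  invisible(x)
}

metrics_row <- function(enrollment, model, m) {
  data.frame(enrollment = enrollment, model = model,
             sensitivity = 100 * m$sensitivity,
             sensitivity_se = 100 * m$se[["sensitivity"]],
             specificity = 100 * m$specificity,
             specificity_se = 100 * m$se[["specificity"]],
             ppv = 100 * m$ppv, ppv_se = 100 * m$se[["ppv"]],
             npv = 100 * m$npv, npv_se = 100 * m$se[["npv"]],
             lr_pos = m$lr_pos, lr_neg = m$lr_neg,
             accuracy = 100 * m$accuracy,
             stringsAsFactors = FALSE)
}

#' Diagnostic-performance report table
#'
#' Assembles the per-model and ensemble performance table: one row per
#' base model (cross-validated, training cohort), one row for the
#' ensemble's cross-validated training performance, and one row for the
#' ensemble applied to the screening cohort. Percentages with binomial
#' SEs; undefined likelihood ratios are `NA` (written as "ND" by
#' [write_performance_csv()]).
#'
#' @param cv_results list of `cv_result` objects (one per model).
#' @param eml_cv optional fitted `eml_model` (or its `ensemble_cv`) for the
#'   training-cohort ensemble row.
#' @param screening_counts optional [confusion_counts()] of the ensemble on
#'   the screening cohort.
#' @return data.frame, one row per model/ensemble entry.
#' @export
performance_table <- function(cv_results, eml_cv = NULL,
                              screening_counts = NULL) {
  rows <- lapply(cv_results, function(cv) {
    cc <- confusion_counts(cv$per_sample$predicted_class, cv$per_sample$label)
    metrics_row("training", cv$model_name, screening_metrics(cc))
  })
  if (!is.null(eml_cv)) {
    ecv <- if (inherits(eml_cv, "eml_model")) eml_cv$ensemble_cv else eml_cv
    cc <- confusion_counts(ecv$per_sample$ensemble_class,
                           ecv$per_sample$label)
    rows <- c(rows, list(metrics_row("training", "EML",
                                     screening_metrics(cc))))
  }
  if (!is.null(screening_counts)) {
    rows <- c(rows, list(metrics_row("test", "EML",
                                     screening_metrics(screening_counts))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the performance report as CSV
#'
#' Numeric cells are rounded to one decimal; undefined entries are "ND".
#'
#' @param report data.frame from [performance_table()].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_performance_csv <- function(report, path) {
  out <- report
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(col) {
    ifelse(is.na(col), "ND", sprintf("%.1f", col))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
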