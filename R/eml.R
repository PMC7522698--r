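#' Signed per-model score
#'
#' One model's contribution to the EC-EML score: its cross-validation
#' accuracy multiplied by the classification confidence of its predicted
#' class, taken as-is for an EC vote and multiplied by -1 for a control
#' vote. With the default `percent` scale the accuracy enters as 0-100, so
#' a single model's score lies in `[-100, 100]`.
#'
#' @param cv_accuracy model cross-validation accuracy in `[0, 1]`.
#' @param confidence confidence of the predicted class in `[0, 1]`.
#' @param predicted_class `"EC"` or `"control"` (vectorized).
#' @param accuracy_scale `"percent"` (default: accuracy enters as 0-100)
#'   or `"fraction"`. Classifications are invariant to the choice.
#' @return Signed numeric score(s).
#' @export
#' @examples
#' compute_model_score(1, 1, "EC")               # +100
#' compute_model_score(1, 1, "control")          # -100
#' compute_model_score(0.9, 0.6, "EC", "fraction") # +0.54
compute_model_score <- function(cv_accuracy, confidence, predicted_class,
                                accuracy_scale = c("percent", "fraction")) {
  accuracy_scale <- match.arg(accuracy_scale)
  check_that(all(cv_accuracy >= 0 & cv_accuracy <= 1), "cv_accuracy",
             "must lie in [0, 1]")
  check_that(all(confidence >= 0 & confidence <= 1), "confidence",
             "must lie in [0, 1]")
  check_that(all(predicted_class %in% c("EC", "control")), "predicted_class",
             "must be 'EC' or 'control'")
  w <- if (accuracy_scale == "percent") 100 * cv_accuracy else cv_accuracy
  sign <- ifelse(predicted_class == "EC", 1, -1)
  sign * w * confidence
}

#' Fit the ensemble machine-learning (EML) model
#'
#' The full training procedure: presence-filter the peaks, fit the
#' preprocessing state (imputation fills, log + z-score scaling), obtain
#' each member's accuracy weight by stratified cross-validation on one
#' shared fold partition (preprocessing re-fitted inside each fold), and
#' refit every member on the complete preprocessed training table. The
#' stored preprocessing state is reused verbatim at screening time, so the
#' deployed signature is fixed by the training cohort.
#'
#' @param table labeled training [feature_table()] (raw intensities,
#'   missing values allowed).
#' @param specs list of [classifier_spec()]s; defaults to all ten models.
#' @param k cross-validation folds for the accuracy weights.
#' @param seed seed for the shared fold partition.
#' @param presence_threshold peak-retention threshold (default 0.75).
#' @param impute_strategy,log_transform preprocessing options.
#' @param accuracy_scale score scale, see [compute_model_score()].
#' @return An `eml_model`: `members` (list of `trained_classifier` +
#'   `cv_accuracy` + full `cv_result`), `prep` (preprocessing state),
#'   `filter_report`, `folds`, `accuracy_scale`, and `ensemble_cv` (the
#'   ensemble's own pooled held-out performance on the training cohort).
#' @export
fit_eml <- function(table, specs = default_classifier_specs(seed), k = 10,
                    seed = 1L, presence_threshold = 0.75,
                    impute_strategy = "half_min", log_transform = TRUE,
                    accuracy_scale = c("percent", "fraction")) {
  stopifnot(inherits(table, "feature_table"))
  accuracy_scale <- match.arg(accuracy_scale)
  check_that(length(specs) >= 2, "specs", "ensemble needs at least 2 members")

  filt <- filter_features(table, presence_threshold)
  ftable <- filt$table
  folds <- make_cv_folds(ftable$labels, k, seed)

  members <- lapply(specs, function(spec) {
    cv <- cross_validate(spec, ftable, folds = folds, preprocess = TRUE,
                         impute_strategy = impute_strategy,
                         log_transform = log_transform)
    list(spec = spec, cv = cv, cv_accuracy = cv$accuracy)
  })
  names(members) <- vapply(members, function(m) m$spec$name, character(1))

  prep <- fit_preprocess(ftable, impute_strategy, log_transform)
  train_prepped <- apply_preprocess(ftable, prep)
  for (i in seq_along(members)) {
    members[[i]]$model <- train_classifier(members[[i]]$spec, train_prepped)
  }

  model <- structure(list(members = members, prep = prep,
                          filter_report = filt$report, folds = folds,
                          accuracy_scale = accuracy_scale),
                     class = "eml_model")

  # Ensemble held-out performance: combine the members' held-out
  # EC-confidences with their accuracy weights (same weighted rule as
  # deployment), so the training-set EML row is itself cross-validated.
  w <- vapply(members, `[[`, numeric(1), "cv_accuracy")
  ec_conf <- vapply(members, function(m) m$cv$per_sample$ec_confidence,
                    numeric(nrow(train_prepped$intensities)))
  pred_cls <- vapply(members, function(m) m$cv$per_sample$predicted_class,
                     character(nrow(train_prepped$intensities)))
  cv_scores <- combine_votes(ec_conf, pred_cls, w, accuracy_scale,
                             sample_id = sample_ids(ftable))
  cv_scores$label <- ftable$labels
  model$ensemble_cv <- list(
    per_sample = cv_scores,
    accuracy = mean(cv_scores$ensemble_class == ftable$labels)
  )
  model
}

#' @export
print.eml_model <- function(x, ...) {
  cat(sprintf("eml_model: %d members, %d features retained (of %d)\n",
              length(x$members), x$filter_report$n_features_kept,
              x$filter_report$n_features_in))
  w <- vapply(x$members, `[[`, numeric(1), "cv_accuracy")
  for (i in seq_along(x$members)) {
    cat(sprintf("  %-20s cv accuracy %.3f\n",
                x$members[[i]]$spec$name, w[i]))
  }
  cat(sprintf("  ensemble held-out accuracy %.3f\n", x$ensemble_cv$accuracy))
  invisible(x)
}

# Weighted combination of member votes. ec_conf and pred_cls are
# n x m matrices (samples x members); w the accuracy weights in [0,1].
combine_votes <- function(ec_conf, pred_cls, w, accuracy_scale,
                          sample_id = NULL) {
  ec_conf <- as.matrix(ec_conf); pred_cls <- as.matrix(pred_cls)
  member_names <- colnames(pred_cls) %||% colnames(ec_conf) %||%
    paste0("m", seq_len(ncol(ec_conf)))
  w_scaled <- if (accuracy_scale == "percent") 100 * w else w
  conf_pred <- ifelse(pred_cls == "EC", ec_conf, 1 - ec_conf)
  signs <- ifelse(pred_cls == "EC", 1, -1)
  model_scores <- sweep(signs * conf_pred, 2, w_scaled, "*")
  score <- rowSums(model_scores)
  wprob <- if (sum(w) > 0) as.numeric(ec_conf %*% w) / sum(w) else
    rep(0.5, nrow(ec_conf))
  out <- data.frame(
    sample_id = sample_id %||% rownames(ec_conf) %||%
      paste0("S", seq_len(nrow(ec_conf))),
    ec_eml_score = score,
    weighted_ec_probability = wprob,
    ensemble_class = ifelse(wprob > 0.5, "EC", "control"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  colnames(model_scores) <- paste0("score_", member_names)
  cbind(out, as.data.frame(model_scores, row.names = FALSE))
}

#' Screen a cohort with a fitted EML model
#'
#' Applies the stored preprocessing (keep-list, training imputation fills,
#' training scaling), collects every member's prediction and confidence,
#' and computes for each sample the per-model signed scores, their sum
#' (the EC-EML score), the accuracy-weighted EC probability
#' `sum(w_i * p_i(EC)) / sum(w_i)`, and the ensemble class call
#' (EC iff weighted EC probability > 50%). Labels in `table`, if any, are
#' never consulted.
#'
#' @param model a fitted `eml_model`.
#' @param table a [feature_table()] whose features cover the model's
#'   keep-list; labels may be `"unknown"`.
#' @return An `eml_screening` data.frame: `sample_id`, `ec_eml_score`,
#'   `weighted_ec_probability`, `ensemble_class`, plus one signed
#'   `score_<model>` column per member.
#' @export
screen_cohort <- function(model, table) {
  stopifnot(inherits(model, "eml_model"), inherits(table, "feature_table"))
  prepped <- apply_preprocess(table, model$prep)
  n <- nrow(prepped$intensities)
  m <- length(model$members)
  ec_conf <- matrix(NA_real_, n, m)
  pred_cls <- matrix(NA_character_, n, m)
  colnames(ec_conf) <- colnames(pred_cls) <-
    vapply(model$members, function(mb) mb$spec$name, character(1))
  for (i in seq_len(m)) {
    out <- predict_confidence(model$members[[i]]$model, prepped)
    ec_conf[, i] <- out$ec_confidence
    pred_cls[, i] <- out$predicted_class
  }
  w <- vapply(model$members, `[[`, numeric(1), "cv_accuracy")
  res <- combine_votes(ec_conf, pred_cls, w, model$accuracy_scale,
                       sample_id = sample_ids(table))
  class(res) <- c("eml_screening", class(res))
  res
}

#' Classify screening results by EC-EML score cutoff
#'
#' The score-based decision device: a sample is called EC iff its EC-EML
#' score strictly exceeds `cutoff`. The default cutoff 0 is the balance
#' point at which the weighted votes for and against EC are equal (a score
#' of exactly 0 is called control). A Youden-optimal cutoff from
#' [roc_analysis()] can be supplied instead.
#'
#' @param results an `eml_screening` from [screen_cohort()], or a numeric
#'   vector of scores.
#' @param cutoff score threshold (default 0).
#' @return Character vector of `"EC"` / `"control"` calls.
#' @export
classify_by_score <- function(results, cutoff = 0) {
  scores <- if (is.numeric(results)) results else results$ec_eml_score
  ifelse(scores > cutoff, "EC", "control")
}

#' Persist / restore a fitted EML model
#'
#' Writes a directory bundle: `model.rds` (serialized state) plus
#' `manifest.json` describing members, weights, the retained feature list
#' and a content hash of the training state.
#'
#' @param model a fitted `eml_model`.
#' @param path bundle directory (created if needed).
#' @return `path` (save) or an `eml_model` (load).
#' @export
save_eml_model <- function(model, path) {
  stopifnot(inherits(model, "eml_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(path, "model.rds"))
  manifest <- list(
    package = "emlscreen",
    class = "eml_model",
    members = lapply(model$members, function(m)
      list(name = m$spec$name, seed = m$spec$seed,
           cv_accuracy = m$cv_accuracy)),
    accuracy_scale = model$accuracy_scale,
    n_features = length(model$prep$feature_ids),
    feature_ids = model$prep$feature_ids,
    state_hash = sum(as.integer(charToRaw(paste(
      model$prep$feature_ids, collapse = "")))) +
      round(sum(model$prep$scaling$mu) * 1e6) %% 2147483647
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_eml_model
#' @export
load_eml_model <- function(path) {
  model <- readRDS(file.path(path, "model.rds"))
  stopifnot(inherits(model, "eml_model"))
  model
}

#' Write screening results to CSV
#'
#' @param results an `eml_screening` from [screen_cohort()].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_screening_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
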