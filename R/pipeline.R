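#' End-to-end run configuration
#'
#' Bundles every stage's settings for [run_screening_study()]: the two
#' cohort configurations (training and screening), the presence filter,
#' cross-validation folds, permutation count and score-cutoff mode, under
#' one global seed that propagates deterministically to every stage
#' (cohort generation, fold partition, permutations) unless a stage
#' config overrides it.
#'
#' The defaults are a screening-study demo: a 50-case / 70-control
#' training cohort and a 1430-woman screening cohort at 16/1430 ~ 1.12%
#' prevalence, 293 peaks of which 25 low-presence, and a class signal
#' strong enough for near-perfect separation.
#'
#' @param seed global integer seed.
#' @param training,screening [cohort_config()]s; defaults derived from
#'   `seed`.
#' @param presence_threshold peak-retention threshold.
#' @param k cross-validation folds.
#' @param n_permutations permutations for the PLS-DA validation.
#' @param cutoff_mode `"zero"` (EC-EML score > 0) or `"youden"` for the
#'   score-based classification reported in the test row.
#' @param classifier_hyperparams per-model hyperparameter overrides, see
#'   [default_classifier_specs()].
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       training = NULL, screening = NULL,
                       presence_threshold = 0.75, k = 10,
                       n_permutations = 1000,
                       cutoff_mode = c("zero", "youden"),
                       classifier_hyperparams = list()) {
  cutoff_mode <- match.arg(cutoff_mode)
  training <- training %||%
    cohort_config(seed = substream_seed(seed, 1))
  screening <- screening %||%
    cohort_config(n_cases = 16, n_controls = 1414,
                  seed = substream_seed(seed, 2))
  stopifnot(inherits(training, "cohort_config"),
            inherits(screening, "cohort_config"))
  check_that(is_count(k) && k >= 2, "k", "must be an integer >= 2")
  check_that(is_count(n_permutations) && n_permutations >= 1,
             "n_permutations", "must be a positive integer")
  structure(list(seed = as.integer(seed), training = training,
                 screening = screening,
                 presence_threshold = presence_threshold, k = k,
                 n_permutations = n_permutations,
                 cutoff_mode = cutoff_mode,
                 classifier_hyperparams = classifier_hyperparams),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  lst <- unclass(config)
  lst$training <- unclass(lst$training)
  lst$screening <- unclass(lst$screening)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$training <- do.call(cohort_config, lst$training)
  lst$screening <- do.call(cohort_config, lst$screening)
  do.call(run_config, lst)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full screening study
#'
#' Orchestrates simulate -> train -> screen -> evaluate: generates (or
#' accepts) a labeled training cohort, fits the ten-member EML with
#' cross-validated accuracy weights, generates (or accepts) a screening
#' cohort whose labels are withheld until evaluation, scores every
#' screening sample, classifies by the weighted-probability rule and by
#' both score cutoffs (0 and Youden-optimal), and evaluates: screening
#' metrics, ROC analysis of the EC-EML score, PLS-DA permutation
#' validation of the training cohort, and the per-model performance table.
#'
#' All outputs are written under `out_dir` together with a manifest
#' (config, seed, versions) sufficient to reproduce the run exactly.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing files.
#' @param training_table,screening_table optional user-supplied
#'   [feature_table()]s replacing simulation (the real-data path).
#' @return A `run_artifacts` list: `model`, `screening_results`,
#'   `roc`, `validation`, `metrics` (per decision rule), `report`,
#'   `config`.
#' @export
run_screening_study <- function(config = run_config(), out_dir = NULL,
                                training_table = NULL,
                                screening_table = NULL) {
  stopifnot(inherits(config, "run_config"))

  training <- stage("simulate-training",
    training_table %||% generate_cohort(config$training))

  model <- stage("train", fit_eml(
    training,
    specs = default_classifier_specs(substream_seed(config$seed, 3),
                                     config$classifier_hyperparams),
    k = config$k, seed = substream_seed(config$seed, 4),
    presence_threshold = config$presence_threshold))

  screening <- stage("simulate-screening",
    screening_table %||% generate_cohort(config$screening))
  screening_blind <- screening
  screening_blind$labels <- rep("unknown", length(screening$labels))

  results <- stage("screen", screen_cohort(model, screening_blind))

  evaluation <- stage("evaluate", {
    truth <- screening$labels
    have_truth <- all(truth %in% c("EC", "control"))
    roc <- validation <- metrics <- report <- youden_cutoff <- NULL
    if (have_truth) {
      roc <- roc_analysis(results$ec_eml_score, truth)
      youden_cutoff <- roc$youden_cutoff
      calls <- list(
        probability = results$ensemble_class,
        score_zero = classify_by_score(results, 0),
        score_youden = classify_by_score(results, youden_cutoff)
      )
      metrics <- lapply(calls, function(cl)
        screening_metrics(confusion_counts(cl, truth)))
      test_counts <- confusion_counts(
        calls[[if (config$cutoff_mode == "zero") "score_zero"
               else "score_youden"]], truth)
      report <- performance_table(lapply(model$members, `[[`, "cv"),
                                  eml_cv = model,
                                  screening_counts = test_counts)
    }
    filtered_training <- subset_features(training, model$prep$feature_ids)
    validation <- plsda_validate(filtered_training,
                                 n_permutations = config$n_permutations,
                                 seed = substream_seed(config$seed, 5))
    list(roc = roc, validation = validation, metrics = metrics,
         report = report, youden_cutoff = youden_cutoff)
  })

  artifacts <- structure(list(model = model,
                              screening_results = results,
                              roc = evaluation$roc,
                              validation = evaluation$validation,
                              metrics = evaluation$metrics,
                              report = evaluation$report,
                              youden_cutoff = evaluation$youden_cutoff,
                              config = config),
                         class = "run_artifacts")

  if (!is.null(out_dir)) {
    stage("write-outputs", {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_feature_table(training, file.path(out_dir, "training.csv"))
      write_feature_table(screening, file.path(out_dir, "screening.csv"))
      write_screening_csv(results, file.path(out_dir, "scores.csv"))
      if (!is.null(evaluation$report)) {
        write_performance_csv(evaluation$report,
                              file.path(out_dir, "report.csv"))
      }
      if (!is.null(evaluation$roc)) {
        write_roc_csv(evaluation$roc, file.path(out_dir, "roc_points.csv"))
      }
      val <- evaluation$validation
      jsonlite::write_json(
        list(r2y = val$r2y, q2y = val$q2y,
             n_permutations = val$n_permutations,
             observed_statistic = val$observed_statistic,
             p_value = val$p_value),
        file.path(out_dir, "validation.json"), auto_unbox = TRUE,
        digits = NA)
      manifest <- list(package = "emlscreen",
                       version = as.character(utils::packageVersion("emlscreen")),
                       r_version = paste(R.version$major, R.version$minor,
                                         sep = "."),
                       seed = config$seed,
                       config = jsonlite::fromJSON(jsonlite::toJSON(
                         unclass(config), auto_unbox = TRUE, digits = NA,
                         force = TRUE)))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }
  artifacts
}

#' @export
print.run_artifacts <- function(x, ...) {
  cat("run_artifacts:\n")
  print(x$model)
  if (!is.null(x$metrics)) {
    cat("\nscreening performance (weighted-probability rule):\n")
    print(x$metrics$probability)
    cat(sprintf("\nEC-EML score AUC %.4f, Youden cutoff %.4g\n",
                x$roc$auc, x$youden_cutoff))
  }
  print(x$validation)
  invisible(x)
}
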