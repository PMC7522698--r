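#' The ten base classification models
#'
#' Names accepted by [classifier_spec()]: decision tree (CART), PLS-DA,
#' naive Bayes, random forest, k-nearest neighbours, single-hidden-layer
#' artificial neural network, RBF support vector machine with Platt-scaled
#' probabilities, linear discriminant analysis, (ridge-penalized) logistic
#' regression, and a deeper multilayer perceptron.
#'
#' @export
CLASSIFIER_NAMES <- c("decision_tree", "plsda", "naive_bayes",
                      "random_forest", "knn", "ann", "svm", "lda",
                      "logistic_regression", "deep_learning")

default_hyperparams <- function(name) {
  switch(name,
    decision_tree = list(maxdepth = 5, minsplit = 5, cp = 0.01),
    plsda = list(ncomp = 5),
    naive_bayes = list(laplace = 0),
    random_forest = list(ntree = 500),
    knn = list(k = 5),
    ann = list(size = 8, decay = 0.1, maxit = 100),
    svm = list(kernel = "radial", cost = 1),
    lda = list(),
    logistic_regression = list(lambda = 0.01),
    deep_learning = list(hidden = c(64, 32, 16), epochs = 200,
                         learning_rate = 0.01, weight_decay = 1e-4),
    stop("unknown classifier name: ", name, call. = FALSE)
  )
}

#' Specify one base classifier
#'
#' @param name one of [CLASSIFIER_NAMES].
#' @param hyperparams named list overriding the model's defaults (see
#'   `emlscreen:::default_hyperparams`).
#' @param seed integer seed controlling any stochastic element of training
#'   (forest bootstrap, network initialization, Platt scaling folds).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(name, hyperparams = list(), seed = 1L) {
  check_that(length(name) == 1 && name %in% CLASSIFIER_NAMES, "name",
             paste("must be one of:", paste(CLASSIFIER_NAMES, collapse = ", ")))
  hp <- utils::modifyList(default_hyperparams(name), hyperparams)
  structure(list(name = name, hyperparams = hp, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' All ten classifier specifications
#'
#' @param seed base seed; each model receives its own derived sub-seed.
#' @param hyperparams optional named list of per-model hyperparameter
#'   overrides, e.g. `list(knn = list(k = 3))`.
#' @return Named list of ten [classifier_spec()] objects.
#' @export
default_classifier_specs <- function(seed = 1L, hyperparams = list()) {
  specs <- lapply(seq_along(CLASSIFIER_NAMES), function(i) {
    nm <- CLASSIFIER_NAMES[i]
    classifier_spec(nm, hyperparams[[nm]] %||% list(),
                    seed = substream_seed(seed, i))
  })
  names(specs) <- CLASSIFIER_NAMES
  specs
}

# Internal: design matrix + label factor with fixed level order
# (control first, EC second => EC is the "positive"/second level).
training_xy <- function(table) {
  y <- factor(table$labels, levels = c("control", "EC"))
  if (anyNA(y)) stop("training table contains 'unknown' labels", call. = FALSE)
  if (anyNA(table$intensities)) {
    stop("training table contains missing values; impute first", call. = FALSE)
  }
  if (any(tabulate(y, 2) < 2)) {
    stop("each class needs at least 2 training samples", call. = FALSE)
  }
  list(x = table$intensities, y = y)
}

# rpart/naiveBayes want data.frames with syntactic names; map features to
# V1..Vp and remember the mapping.
vframe <- function(x) {
  df <- as.data.frame(x)
  colnames(df) <- paste0("V", seq_len(ncol(x)))
  df
}

#' Train one base classifier
#'
#' Fits the model named in `spec` on a fully preprocessed (imputed, scaled)
#' labeled table. Training is deterministic given `spec$seed`. The exact
#' feature list and order is recorded for alignment at prediction time.
#'
#' @param spec a [classifier_spec()].
#' @param table a labeled, complete [feature_table()].
#' @return A `trained_classifier`.
#' @export
train_classifier <- function(spec, table) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(table, "feature_table"))
  d <- training_xy(table)
  x <- d$x; y <- d$y
  hp <- spec$hyperparams
  y01 <- as.numeric(y) - 1  # EC = 1

  fit <- with_seed(spec$seed, switch(spec$name,
    decision_tree = {
      df <- vframe(x); df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = hp$maxdepth,
                                                  minsplit = hp$minsplit,
                                                  cp = hp$cp))
    },
    plsda = {
      ncomp <- min(hp$ncomp, nrow(x) - 2L, ncol(x))
      pf <- mixOmics::plsda(x, y, ncomp = ncomp)
      scores <- pf$variates$X
      post <- suppressWarnings(MASS::lda(scores, grouping = y))
      list(pls = pf, posterior = post, ncomp = ncomp)
    },
    naive_bayes = e1071::naiveBayes(vframe(x), y, laplace = hp$laplace),
    random_forest = randomForest::randomForest(x = x, y = y, ntree = hp$ntree),
    knn = list(x = x, y = y, k = hp$k),
    ann = nnet::nnet(x, y01, size = hp$size, decay = hp$decay,
                     maxit = hp$maxit, entropy = TRUE, trace = FALSE,
                     MaxNWts = 1e6),
    svm = e1071::svm(x, y, kernel = hp$kernel, cost = hp$cost,
                     probability = TRUE),
    lda = suppressWarnings(MASS::lda(x, grouping = y)),
    logistic_regression = {
      xg <- if (ncol(x) == 1) cbind(x, .pad = 0) else x
      glmnet::glmnet(xg, y, family = "binomial", alpha = 0,
                     lambda = hp$lambda)
    },
    deep_learning = mlp_fit(x, y01, hidden = hp$hidden, epochs = hp$epochs,
                            learning_rate = hp$learning_rate,
                            weight_decay = hp$weight_decay, seed = spec$seed)
  ))

  structure(list(spec = spec, fit = fit, feature_ids = colnames(x)),
            class = "trained_classifier")
}

# EC-class probability for each row of matrix `x` (columns already aligned
# to model$feature_ids).
ec_probability <- function(model, x) {
  fit <- model$fit
  spec <- model$spec
  p <- switch(spec$name,
    decision_tree = stats::predict(fit, vframe(x), type = "prob")[, "EC"],
    plsda = {
      scores <- stats::predict(fit$pls, x)$variates
      colnames(scores) <- colnames(fit$pls$variates$X)
      stats::predict(fit$posterior, scores)$posterior[, "EC"]
    },
    naive_bayes = stats::predict(fit, vframe(x), type = "raw")[, "EC"],
    random_forest = stats::predict(fit, x, type = "prob")[, "EC"],
    knn = with_seed(spec$seed, {
      pred <- class::knn(fit$x, x, cl = fit$y, k = fit$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "EC", win, 1 - win)
    }),
    ann = as.numeric(stats::predict(fit, x)),
    svm = {
      pr <- stats::predict(fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "EC"]
    },
    lda = stats::predict(fit, x)$posterior[, "EC"],
    logistic_regression = {
      xg <- if (ncol(x) == 1) cbind(x, .pad = 0) else x
      as.numeric(stats::predict(fit, xg, type = "response"))
    },
    deep_learning = mlp_predict(fit, x)
  )
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Predict class and confidence
#'
#' Applies a trained classifier to a table preprocessed with the training
#' parameters. The classification confidence is the class-membership
#' probability of the predicted class; the two class confidences always
#' sum to 1. A sample is called EC iff its EC-probability exceeds 0.5
#' (an exact tie goes to control, favouring specificity in screening).
#'
#' @param model a `trained_classifier`.
#' @param table a complete [feature_table()] whose features cover the
#'   model's training features.
#' @return data.frame with `sample_id`, `predicted_class`,
#'   `ec_confidence`, `confidence` (probability of the predicted class).
#' @export
predict_confidence <- function(model, table) {
  stopifnot(inherits(model, "trained_classifier"),
            inherits(table, "feature_table"))
  absent <- setdiff(model$feature_ids, feature_ids(table))
  if (length(absent)) {
    stop("table lacks features required by the model: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  x <- table$intensities[, model$feature_ids, drop = FALSE]
  if (anyNA(x)) stop("prediction table contains missing values", call. = FALSE)
  ec <- ec_probability(model, x)
  cls <- ifelse(ec > 0.5, "EC", "control")
  data.frame(sample_id = sample_ids(table),
             predicted_class = cls,
             ec_confidence = ec,
             confidence = ifelse(cls == "EC", ec, 1 - ec),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `k` folds, stratified by class so every
#' fold sees both classes. The assignment depends only on the labels and
#' the seed, so all ten models can be cross-validated on an identical
#' partition (making their accuracy weights comparable).
#'
#' @param labels per-sample class labels.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_cv_folds <- function(labels, k = 10, seed = 1L) {
  check_that(is_count(k) && k >= 2, "k", "must be an integer >= 2")
  labels <- as.character(labels)
  smallest <- min(table(labels))
  if (smallest < k) {
    stop(sprintf("smallest class has %d samples < k = %d folds; use a smaller k",
                 smallest, k), call. = FALSE)
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Cross-validate one classifier
#'
#' Stratified k-fold cross-validation with no leakage: when
#' `preprocess = TRUE` the imputation fills and scaling parameters are
#' re-fitted inside each training fold and applied to its held-out fold.
#' Accuracy is the fraction of correct held-out predictions pooled over
#' all samples (each sample held out exactly once).
#'
#' @param spec a [classifier_spec()].
#' @param table a labeled [feature_table()]; raw (possibly missing) if
#'   `preprocess = TRUE`, fully preprocessed otherwise.
#' @param k number of folds.
#' @param seed seed for the fold partition.
#' @param folds optional precomputed fold assignment (from
#'   [make_cv_folds()]), shared across models.
#' @param preprocess re-fit imputation/scaling within each fold.
#' @param impute_strategy,log_transform preprocessing options when
#'   `preprocess = TRUE`.
#' @return A `cv_result`: `model_name`, `k`, `accuracy`, `accuracy_se`,
#'   and `per_sample` (held-out predictions and EC-confidences).
#' @export
cross_validate <- function(spec, table, k = 10, seed = 1L, folds = NULL,
                           preprocess = FALSE,
                           impute_strategy = "half_min",
                           log_transform = TRUE) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(table, "feature_table"))
  if (is.null(folds)) folds <- make_cv_folds(table$labels, k, seed)
  k <- max(folds)
  n <- nrow(table$intensities)
  pred <- character(n); conf <- numeric(n)
  for (f in seq_len(k)) {
    hold <- which(folds == f)
    train <- subset_samples(table, -hold)
    test <- subset_samples(table, hold)
    if (preprocess) {
      prep <- fit_preprocess(train, impute_strategy, log_transform)
      train <- apply_preprocess(train, prep)
      test <- apply_preprocess(test, prep)
    }
    model <- train_classifier(spec, train)
    out <- predict_confidence(model, test)
    pred[hold] <- out$predicted_class
    conf[hold] <- out$ec_confidence
  }
  correct <- pred == table$labels
  acc <- mean(correct)
  structure(list(model_name = spec$name, k = k,
                 accuracy = acc,
                 accuracy_se = sqrt(acc * (1 - acc) / n),
                 per_sample = data.frame(sample_id = sample_ids(table),
                                         label = table$labels,
                                         fold = folds,
                                         predicted_class = pred,
                                         ec_confidence = conf,
                                         stringsAsFactors = FALSE)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %s, %d-fold, accuracy %.3f (SE %.3f)\n",
              x$model_name, x$k, x$accuracy, x$accuracy_se))
  invisible(x)
}
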