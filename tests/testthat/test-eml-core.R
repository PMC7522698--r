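test_that("model scores multiply accuracy by confidence with the control sign flip", {
  expect_equal(compute_model_score(1, 1, "EC"), 100)
  expect_equal(compute_model_score(1, 1, "control"), -100)
  expect_equal(compute_model_score(0.9, 0.6, "EC", "fraction"), 0.54)
  expect_equal(compute_model_score(c(0.8, 0.8), c(0.5, 0.5), c("EC", "control")),
               c(40, -40))
  expect_error(compute_model_score(1.2, 0.5, "EC"), "cv_accuracy")
  expect_error(compute_model_score(0.9, -0.1, "EC"), "confidence")
  expect_error(compute_model_score(0.9, 0.5, "case"), "predicted_class")
})

# direct access to the vote combiner for enumerated-grid checks
combine <- function(ec_conf, pred_cls, w, scale = "percent") {
  emlscreen:::combine_votes(ec_conf, pred_cls, w, scale)
}

test_that("opposite unanimous votes with equal weight and confidence tie to control", {
  res <- combine(cbind(a = 0.9, b = 0.1), cbind(a = "EC", b = "control"),
                 c(0.8, 0.8))
  expect_equal(res$weighted_ec_probability, 0.5)
  expect_equal(res$ensemble_class, "control")
  expect_equal(res$ec_eml_score, 0)
})

test_that("weighted EC probability equals the hand-computed normalized sum", {
  set.seed(8)
  for (i in 1:20) {
    m <- sample(2:10, 1)
    w <- runif(m)
    conf <- matrix(runif(5 * m), 5, m)
    cls <- matrix(sample(c("EC", "control"), 5 * m, TRUE), 5, m)
    colnames(conf) <- colnames(cls) <- paste0("m", 1:m)
    res <- combine(conf, cls, w)
    manual_wprob <- as.numeric(conf %*% w) / sum(w)
    expect_equal(res$weighted_ec_probability, manual_wprob)
    manual_score <- sapply(1:5, function(s) {
      sum(compute_model_score(w, ifelse(cls[s, ] == "EC", conf[s, ],
                                        1 - conf[s, ]), cls[s, ]))
    })
    expect_equal(res$ec_eml_score, manual_score)
    # the summed score equals the sum of the per-model score columns exactly
    expect_equal(res$ec_eml_score,
                 rowSums(res[, grep("^score_", names(res)), drop = FALSE]))
  }
})

test_that("a zero-weight member never changes scores or calls", {
  conf <- cbind(a = c(0.9, 0.2), b = c(0.7, 0.4))
  cls <- cbind(a = c("EC", "control"), b = c("EC", "control"))
  base <- combine(conf, cls, c(0.9, 0.6))
  extended <- combine(cbind(conf, z = c(0.99, 0.01)),
                      cbind(cls, z = c("EC", "EC")), c(0.9, 0.6, 0))
  expect_equal(extended$ec_eml_score, base$ec_eml_score)
  expect_equal(extended$weighted_ec_probability, base$weighted_ec_probability)
  expect_equal(extended$ensemble_class, base$ensemble_class)
})

test_that("raising one member's EC confidence never lowers score or probability", {
  set.seed(15)
  for (i in 1:10) {
    m <- 6
    w <- runif(m)
    conf <- matrix(runif(m), 1, m, dimnames = list(NULL, paste0("m", 1:m)))
    grid <- seq(0, 1, by = 0.05)
    scores <- probs <- numeric(length(grid))
    for (g in seq_along(grid)) {
      cj <- conf; cj[1, 3] <- grid[g]
      cls <- ifelse(cj > 0.5, "EC", "control")
      res <- combine(cj, cls, w)
      scores[g] <- res$ec_eml_score
      probs[g] <- res$weighted_ec_probability
    }
    expect_true(all(diff(scores) >= -1e-12))
    expect_true(all(diff(probs) >= -1e-12))
  }
})

test_that("the score respects the triangle bound, with equality only at full confidence", {
  set.seed(22)
  w <- runif(10)
  conf <- matrix(runif(10), 1, 10, dimnames = list(NULL, paste0("m", 1:10)))
  cls <- ifelse(conf > 0.5, "EC", "control")
  res <- combine(conf, cls, w)
  expect_lt(abs(res$ec_eml_score), sum(100 * w))
  all_in <- combine(matrix(1, 1, 10, dimnames = list(NULL, paste0("m", 1:10))),
                    matrix("EC", 1, 10), w)
  expect_equal(all_in$ec_eml_score, sum(100 * w))
})

test_that("probability rule and score sign agree for equal weights and symmetric confidences", {
  # exhaustive grid: 10 members, each voting EC with confidence p or
  # control with confidence 1-p; equal weights
  # binary-exact confidences keep the 5-vs-5 tie exact in floating point
  grid <- expand.grid(p = c(0.625, 0.75, 0.9375), n_ec = 0:10)
  for (r in seq_len(nrow(grid))) {
    p <- grid$p[r]; n_ec <- grid$n_ec[r]
    ec_conf <- matrix(c(rep(p, n_ec), rep(1 - p, 10 - n_ec)), 1, 10,
                      dimnames = list(NULL, paste0("m", 1:10)))
    cls <- matrix(c(rep("EC", n_ec), rep("control", 10 - n_ec)), 1, 10)
    res <- combine(ec_conf, cls, rep(0.5, 10))
    expect_equal(res$ensemble_class == "EC", res$ec_eml_score > 0,
                 info = sprintf("p=%.2f n_ec=%d", p, n_ec))
  }
})

test_that("score-cutoff classification uses a strict inequality at the boundary", {
  expect_equal(classify_by_score(c(0, -500, 300), 0),
               c("control", "control", "EC"))
  res <- data.frame(ec_eml_score = c(-1, 2))
  expect_equal(classify_by_score(res), c("control", "EC"))
})

test_that("a perfectly separable cohort trains an error-free ensemble", {
  # no dropout: half-min imputation of a missing informative peak would
  # legitimately push single-feature learners off an otherwise clean case
  coh <- small_cohort(n_cases = 25, n_controls = 25, p = 20,
                      n_informative = 10, effect_size = 8,
                      low_presence = 2, missing_rate = 0, seed = 17)
  model <- fit_eml(coh, specs = default_classifier_specs(5), k = 5, seed = 5)
  w <- vapply(model$members, `[[`, numeric(1), "cv_accuracy")
  expect_equal(unname(w), rep(1, 10))
  expect_equal(model$ensemble_cv$accuracy, 1.0)

  # deployment on an identically structured independent cohort is also
  # error-free, and scores are far from the zero cutoff
  screen <- generate_cohort(cohort_config(n_cases = 10, n_controls = 40,
                                          n_features = 20, n_informative = 10,
                                          effect_size = 8, missing_rate = 0,
                                          low_presence_features = 2,
                                          seed = 18))
  res <- screen_cohort(model, screen)
  expect_equal(res$ensemble_class, ifelse(screen$labels == "EC", "EC", "control"))
  expect_identical(classify_by_score(res, 0), res$ensemble_class)
})

test_that("screening results and fitted models survive a save/load round trip", {
  coh <- small_cohort(n_cases = 12, n_controls = 15, p = 12,
                      n_informative = 5, low_presence = 1, seed = 23)
  specs <- default_classifier_specs(3)[c("knn", "lda", "logistic_regression")]
  model <- fit_eml(coh, specs = specs, k = 3, seed = 3)
  dir <- withr::local_tempdir()
  save_eml_model(model, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  reloaded <- load_eml_model(dir)
  probe <- small_cohort(n_cases = 5, n_controls = 5, p = 12,
                        n_informative = 5, low_presence = 1, seed = 24)
  expect_equal(screen_cohort(reloaded, probe), screen_cohort(model, probe))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(unname(vapply(manifest$members, `[[`, "", "name")),
               unname(vapply(specs, `[[`, "", "name")))
})

test_that("ensembles reject fewer than two members", {
  coh <- small_cohort(seed = 2)
  expect_error(fit_eml(coh, specs = default_classifier_specs(1)["knn"]),
               "specs")
})
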