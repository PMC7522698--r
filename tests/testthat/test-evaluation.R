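test_that("screening metrics reproduce a low-prevalence confusion matrix exactly", {
  m <- screening_metrics(tp = 16, fp = 2, fn = 0, tn = 1412)
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$ppv, 16 / 18)
  expect_equal(round(100 * m$ppv, 1), 88.9)
  expect_equal(m$specificity, 1412 / 1414)
  expect_equal(round(100 * m$specificity, 2), 99.86)
  expect_equal(round(100 * m$specificity, 1), 99.9)
  expect_equal(m$accuracy, 1428 / 1430)
  expect_equal(round(100 * m$accuracy, 2), 99.86)
  expect_equal(m$npv, 1.0)
  expect_equal(m$lr_pos, 707.0)
  expect_equal(m$lr_neg, 0.0)
  expect_equal(round(100 * m$prevalence, 2), 1.12)
})

test_that("a perfect test reports LR+ as undefined, never as a number", {
  m <- screening_metrics(tp = 10, fp = 0, fn = 0, tn = 10)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$npv, 1)
  expect_true(is.na(m$lr_pos))
  expect_equal(m$lr_neg, 0)
})

test_that("metrics match a first-principles recount on random confusion tables", {
  set.seed(77)
  for (i in 1:200) {
    counts <- rmultinom(1, sample(10:500, 1), prob = runif(4, 0.05, 1))[, 1]
    tp <- counts[1]; fp <- counts[2]; fn <- counts[3]; tn <- counts[4]
    m <- screening_metrics(tp = tp, fp = fp, fn = fn, tn = tn)
    # oracle: rebuild the predictions and recount with table()
    truth <- rep(c("EC", "EC", "control", "control"), c(tp, fn, fp, tn))
    pred <- rep(c("EC", "control", "EC", "control"), c(tp, fn, fp, tn))
    sens_o <- if (tp + fn > 0) mean(pred[truth == "EC"] == "EC") else NA_real_
    spec_o <- if (tn + fp > 0) mean(pred[truth == "control"] == "control") else NA_real_
    expect_equal(m$sensitivity, sens_o)
    expect_equal(m$specificity, spec_o)
    expect_equal(m$accuracy, mean(pred == truth))
    expect_equal(m$prevalence, mean(truth == "EC"))
    if (!is.na(spec_o) && spec_o < 1) expect_equal(m$lr_pos, sens_o / (1 - spec_o))
    if (!is.na(m$ppv)) expect_equal(m$ppv, mean(truth[pred == "EC"] == "EC"))
  }
  expect_error(screening_metrics(tp = 0, fp = 0, fn = 0, tn = 0), "counts")
})

test_that("separated scores give AUC 1 with the Youden cutoff strictly between the groups", {
  scores <- c(rnorm(20, 10), rnorm(30, 0))
  labels <- rep(c("EC", "control"), c(20, 30))
  r <- roc_analysis(scores, labels)
  expect_equal(r$auc, 1.0)
  expect_equal(r$youden_j, 1.0)
  expect_gt(r$youden_cutoff, max(scores[labels == "control"]))
  expect_lt(r$youden_cutoff, min(scores[labels == "EC"]))
})

test_that("uninformative scores give chance-level AUC", {
  set.seed(5)
  scores <- rnorm(2000)
  labels <- sample(rep(c("EC", "control"), 1000))
  expect_lt(abs(roc_analysis(scores, labels)$auc - 0.5), 0.04)
})

test_that("AUC equals the exhaustive Mann-Whitney pair count, ties included", {
  set.seed(31)
  for (i in 1:20) {
    n_case <- sample(3:25, 1); n_ctrl <- sample(3:25, 1)
    # coarse grid forces ties within and across groups
    scores <- sample(seq(0, 5, by = 0.5), n_case + n_ctrl, replace = TRUE)
    labels <- rep(c("EC", "control"), c(n_case, n_ctrl))
    expect_equal(roc_analysis(scores, labels)$auc, oracle_auc(scores, labels))
  }
})

test_that("the Youden sweep matches brute-force threshold maximization", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(50:200, 1)
    labels <- rep(c("EC", "control"), c(ceiling(n / 3), n - ceiling(n / 3)))
    scores <- rnorm(n) + 1.5 * (labels == "EC")
    r <- roc_analysis(scores, labels)
    # oracle: evaluate J over every midpoint between consecutive distinct
    # scores plus sentinels outside the range
    s <- sort(unique(scores))
    cands <- c(min(s) - 1, (s[-1] + s[-length(s)]) / 2, max(s) + 1)
    j_oracle <- vapply(cands, function(t) {
      mean(scores[labels == "EC"] > t) + mean(scores[labels == "control"] <= t) - 1
    }, numeric(1))
    expect_equal(r$youden_j, max(j_oracle), tolerance = 1e-12)
    # the returned cutoff achieves the maximal J under the score > t rule
    j_at_cut <- mean(scores[labels == "EC"] > r$youden_cutoff) +
      mean(scores[labels == "control"] <= r$youden_cutoff) - 1
    expect_equal(j_at_cut, max(j_oracle), tolerance = 1e-12)
  }
})

test_that("ROC coordinates are monotone and AUC is rank-invariant", {
  set.seed(3)
  labels <- rep(c("EC", "control"), c(40, 60))
  scores <- rnorm(100) + (labels == "EC")
  r <- roc_analysis(scores, labels)
  ord <- order(r$thresholds)
  expect_true(all(diff(r$fpr[ord]) <= 1e-12))
  expect_true(all(diff(r$tpr[ord]) <= 1e-12))
  expect_equal(roc_analysis(exp(scores / 2), labels)$auc, r$auc)
})

test_that("DeLong comparison is null for identical scores and antisymmetric under label swap", {
  set.seed(9)
  labels <- rep(c("EC", "control"), c(40, 40))
  a <- rnorm(80) + (labels == "EC")
  same <- delong_test(a, a, labels)
  expect_equal(same$auc_a, same$auc_b)
  expect_equal(same$p_value, 1)

  b <- a + rnorm(80, sd = 0.7)
  d1 <- delong_test(a, b, labels)
  swapped <- ifelse(labels == "EC", "control", "EC")
  d2 <- delong_test(-a, -b, swapped)
  expect_equal(d2$z, d1$z, tolerance = 1e-9)
  expect_equal(d2$p_value, d1$p_value, tolerance = 1e-9)
})

test_that("DeLong variance tracks the bootstrap variance of the AUC", {
  set.seed(41)
  n <- 100
  labels <- rep(c("EC", "control"), c(n, n))
  scores <- rnorm(2 * n) + 1 * (labels == "EC")
  d <- delong_test(scores, scores + rnorm(2 * n, sd = 2), labels)

  case_scores <- scores[labels == "EC"]
  ctrl_scores <- scores[labels == "control"]
  boot <- vapply(1:2000, function(b) {
    cs <- sample(case_scores, n, replace = TRUE)
    ct <- sample(ctrl_scores, n, replace = TRUE)
    # rank-based Mann-Whitney AUC, independent of the package's ROC path
    r <- rank(c(cs, ct))
    (sum(r[1:n]) - n * (n + 1) / 2) / (n * n)
  }, numeric(1))
  expect_lt(abs(d$variance_a - var(boot)) / var(boot), 0.15)
})

test_that("PLS-DA validation: Q2Y never beats R2Y and a separable cohort reaches the minimal p", {
  for (s in 1:6) {
    coh <- small_cohort(n_cases = 12, n_controls = 12, p = 15,
                        n_informative = 5, effect_size = 1,
                        low_presence = 0, seed = 300 + s)
    v <- plsda_validate(coh, n_components = 3, n_permutations = 2, seed = s)
    expect_lte(v$q2y, v$r2y)
    expect_lte(v$r2y, 1)
  }

  sep <- small_cohort(n_cases = 30, n_controls = 30, p = 20,
                      n_informative = 8, effect_size = 5,
                      low_presence = 0, missing_rate = 0, seed = 55)
  v <- plsda_validate(sep, n_components = 5, n_permutations = 999, seed = 2)
  expect_equal(v$p_value, 1 / 1000)
  expect_equal(v$p_value,
               (1 + sum(v$permuted_statistics >= v$observed_statistic)) /
                 (v$n_permutations + 1))
  expect_gt(v$r2y, 0.8)
  expect_gt(v$q2y, 0.8)
})

test_that("the performance table mirrors its inputs and round-trips through CSV", {
  tab <- scale_features(toy_table(n_cases = 12, n_controls = 12, p = 5,
                                  shift = 2.5))$table
  cvs <- lapply(c("knn", "lda"), function(nm)
    cross_validate(classifier_spec(nm), tab, k = 4, seed = 1))
  counts <- confusion_counts(rep(c("EC", "control"), c(18, 1412)),
                             rep(c("EC", "control"), c(16, 1414)))
  report <- performance_table(cvs, screening_counts = counts)
  expect_equal(nrow(report), 3)
  expect_equal(report$model, c("knn", "lda", "EML"))
  test_row <- report[report$enrollment == "test", ]
  expect_equal(round(test_row$lr_pos, 1), 707.0)
  expect_equal(round(test_row$accuracy, 1), 99.9)

  # perfect-classifier rows render LR+ as "ND"
  perfect <- performance_table(list(), screening_counts = screening_metrics(
    tp = 10, fp = 0, fn = 0, tn = 10)$counts |>
      (\(x) confusion_counts(rep(c("EC", "control"), c(10, 10)),
                             rep(c("EC", "control"), c(10, 10))))())
  csv <- withr::local_tempfile(fileext = ".csv")
  write_performance_csv(rbind(report, perfect), csv)
  parsed <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(parsed$lr_pos[nrow(parsed)], "ND")
  # numeric cells reproduce the inputs at the printed precision
  expect_equal(as.numeric(parsed$sensitivity[1:3]),
               round(report$sensitivity, 1))
  expect_equal(as.numeric(parsed$lr_pos[3]), round(report$lr_pos[3], 1))
})

test_that("single-class inputs are rejected", {
  expect_error(roc_analysis(rnorm(5), rep("EC", 5)), "classes")
  expect_error(plsda_validate(feature_table(matrix(rlnorm(20), 5, 4),
                                            rep("EC", 5))),
               "two labeled classes")
})
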