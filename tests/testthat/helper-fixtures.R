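# Small in-code fixtures shared across test files.

# Complete (no-missing) two-class table on the preprocessed scale:
# standard-normal features, first `n_informative` shifted by `shift` in
# cases. Suitable for direct train_classifier / cross_validate calls
# (preprocess = FALSE).
toy_table <- function(n_cases = 15, n_controls = 15, p = 5,
                      n_informative = 2, shift = 3, seed = 42) {
  set.seed(seed)
  n <- n_cases + n_controls
  x <- matrix(rnorm(n * p), n, p)
  if (n_informative > 0 && shift != 0) {
    x[seq_len(n_cases), seq_len(n_informative)] <-
      x[seq_len(n_cases), seq_len(n_informative)] + shift
  }
  colnames(x) <- paste0("F", seq_len(p))
  # shift to positive range so the same fixture also works on the raw path
  feature_table(x - min(x) + 1, rep(c("EC", "control"), c(n_cases, n_controls)))
}

# Raw-scale cohort straight from the generator, small enough for fast CV.
small_cohort <- function(n_cases = 20, n_controls = 25, p = 30,
                         n_informative = 8, effect_size = 2.5,
                         low_presence = 3, missing_rate = 0.05, seed = 7) {
  generate_cohort(cohort_config(
    n_cases = n_cases, n_controls = n_controls, n_features = p,
    n_informative = n_informative, effect_size = effect_size,
    low_presence_features = low_presence, missing_rate = missing_rate,
    seed = seed))
}

# Rank-based AUC used as an independent oracle (Mann-Whitney pair count
# with half-credit for ties), never calling the package's ROC path.
oracle_auc <- function(scores, labels) {
  case <- scores[labels == "EC"]
  ctrl <- scores[labels == "control"]
  pairs <- outer(case, ctrl, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}
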