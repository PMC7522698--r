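---
title: "Methods: accuracy-weighted ensemble screening from blood metabolomes"
author: "emlscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accuracy-weighted ensemble screening from blood metabolomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The screening problem

Endometrial carcinoma (EC) has no validated population screening test.
Serum metabolomes measured by GC-MS — a few hundred peak intensities per
dried-blood-spot sample — carry a multivariate signature that separates EC
cases from controls, and a classifier trained on a modest case-control
cohort can then be deployed on a large unselected screening population in
which disease prevalence is on the order of 1%. At such prevalence the
operating point matters enormously: a specificity of 99.9% versus 98%
is the difference between 2 and 30 false positives per ~1400 women
screened, each triggering an endometrial biopsy.

`emlscreen` implements this workflow end to end: peak-table quality
filtering, preprocessing, an ensemble of ten classifiers combined by
accuracy-weighted soft voting, a signed continuous marker (the EC-EML
score), and the full diagnostic evaluation layer. Because the original
serum metabolomes are not publicly deposited, the package ships a
synthetic cohort generator with the same statistical geometry, so that
every stage is testable and every number in the documentation is
recomputable from code.

# The ensemble model

## Base models and confidences

Ten classifiers are trained on the same preprocessed table: CART decision
tree, PLS-DA, Gaussian naive Bayes, random forest, k-nearest neighbours,
a single-hidden-layer neural network, an RBF-kernel SVM, linear
discriminant analysis, ridge-penalized logistic regression, and a deeper
multilayer perceptron. Each model exposes one uniform contract: for any
sample it returns a class call and a *classification confidence* — the
membership probability of the predicted class, in [0, 1], with the two
class probabilities summing to 1.

Where a model is not natively probabilistic, the confidence is defined
explicitly: the k-NN confidence is the neighbour vote fraction; the SVM
probability comes from Platt scaling; PLS-DA and LDA use the Gaussian
posterior over the discriminant scores. A sample is called EC iff its EC
probability exceeds 0.5; an exact tie goes to control, which favours
specificity — the right default for a screening test whose positives are
confirmed by biopsy.

## Accuracy weights

Each model's weight is its stratified k-fold cross-validation accuracy on
the training cohort (k = 10 by default). One fold partition, fixed by the
seed and shared by all ten models, makes the weights comparable.
Imputation and scaling parameters are re-fitted inside each training fold
and applied to its held-out fold, so the weights are leakage-free. After
cross-validation every member is refitted on the full training table.

## The EC-EML score and the two decision rules

For each screened sample, model *i* with weight \(w_i\) (entered on the
0–100 scale by default) and predicted-class confidence \(c_i\) contributes
the signed score

\[ s_i = \pm\, w_i\, c_i, \]

positive when the model votes EC and negative when it votes control. The
EC-EML score is \(\sum_i s_i\); with ten members on the percent scale it
lives in [-1000, 1000]. Two decision devices are provided, mirroring how
such ensembles are reported:

* the **weighted-probability rule** (default): the sample is EC iff
  \(\sum_i w_i\, p_i(\mathrm{EC}) / \sum_i w_i > 0.5\);
* the **score cutoff**: EC iff the EC-EML score strictly exceeds a
  cutoff, either 0 (the balance point between votes for and against) or
  the Youden-optimal cutoff from the ROC sweep.

When all weights are equal and confidences are complementary the two
rules coincide; the package tests this by grid enumeration. The score
scale (percent vs fraction accuracy) never changes any classification —
only the printed magnitude of the score and its cutoffs.

# The synthetic cohort generator

The generator emulates the study geometry the analysis assumes:

* a training cohort of 50 EC cases vs 70 controls and a screening cohort
  of 1430 samples at 16/1430 ≈ 1.12% prevalence;
* 293 detected peaks of which 25 are engineered to fall below the 75%
  presence filter, leaving 268;
* log-normal intensities (normal on the log scale, sd 1, exponentiated),
  since GC-MS peak areas are positive and right-skewed;
* a class signal as an additive log-scale shift (`effect_size`, in sd
  units) on `n_informative` peaks (20 by default);
* missing-completely-at-random dropout (5% by default), with an optional
  left-censoring mode for below-detection-limit emulation, and an
  optional equicorrelated-block mode for robustness checks (independent
  features by default — no published covariance exists to emulate).

Two generator choices deserve comment. First, each peak draws from its
own deterministically derived random sub-stream, so enlarging the panel
never perturbs previously generated columns — convenient for
reproducible experiments. Second, the default `effect_size` is 2.5:
with 20 informative peaks this puts the oracle linear rule's error
essentially at zero while leaving the weaker learners (CART, LDA)
visibly imperfect, which reproduces the published regime — an ensemble
with error-free cross-validation built from members spanning roughly
83–100% accuracy, and one-to-few false positives per ~1400 screened.
Under the closed-form normal theory the oracle error per class is
\(\Phi(-\sqrt{m}\,\delta/2)\) for \(m\) informative peaks of shift
\(\delta\); the generator's tests verify this against Monte-Carlo
simulation, and the parameter-recovery test designs \((m, \delta)\) for a
target Bayes sensitivity/specificity of 0.9 and checks the fitted
ensemble lands within ±0.05 of it.

What the generator does **not** emulate: real peak-intensity
correlation structure, batch and drift effects, biological covariate
coupling (demographics are simulated independently of the metabolome),
or the identity of any actual metabolite. Passing tests on these
cohorts therefore validate the *pipeline machinery* — filtering,
leakage-free weighting, score arithmetic, evaluation statistics — not
the clinical performance of any real signature.

# Preprocessing decisions

* **Presence filter**: a peak is kept iff observed in at least 75% of
  training samples (inclusive boundary). Only presence is computable
  from a feature table; "spectral quality" exclusions need raw spectra
  and are represented solely by the zero-variance rule.
* **Keep-list deployment**: the filter is fitted on the training cohort
  and the resulting keep-list is applied verbatim to screening data —
  the deployed signature does not re-adapt to the screening cohort.
* **Imputation**: half the feature's minimum observed value (the
  standard below-detection-limit convention); feature-median available.
* **Scaling**: natural log, then per-feature z-scoring. Parameters are
  fitted on training data only and replayed on screening data.
  Total-ion-current style normalization is deliberately absent
  (`log_transform` can be disabled; nothing in the published analysis
  indicates TIC normalization).

# Hyperparameter defaults

No hyperparameters are published, so defaults are conventional:
CART depth ≤ 5; random forest 500 trees; k-NN k = 5 (Euclidean); SVM
RBF with C = 1 and Platt probabilities; PLS-DA 5 components (the
component count reported as best-performing); ridge-logistic
λ = 0.01 (a plain GLM is degenerate at p ≈ 268 > n = 120); LDA and
Gaussian naive Bayes standard. The neural-network member uses 8 hidden
units (maxit 100, decay 0.1): at ~270 inputs the quasi-Newton optimiser
behind larger single-layer networks costs tens of seconds per fit for no
accuracy gain on these cohorts, and 8 units already reach the
separable-data ceiling. The deep member is a 64-32-16 ReLU multilayer
perceptron with a logistic output, trained by full-batch Adam
(200 epochs, lr 0.01, L2 1e-4) — implemented in the package and fully
seeded, so it is distinguished from the shallow network by depth, as the
ten-model bank requires. Every default is overridable per model.

# Evaluation layer

* **Confusion metrics** follow the textbook formulas (sensitivity,
  specificity, PPV, NPV, accuracy, LR±, prevalence), each with a
  binomial standard error on its own denominator. Any metric with a
  zero denominator is *undefined* and reported as "ND" — notably LR+ at
  specificity 1 — never coerced to 0 or 1.
* **ROC/AUC** ride on pROC; the AUC is the Mann-Whitney rank statistic,
  and the package's tests verify it against exhaustive pair counting.
  The Youden cutoff maximizes sensitivity + specificity − 1 over the
  threshold sweep of the rule `score > t`, ties broken toward higher
  specificity; a brute-force midpoint maximization is the test oracle.
* **DeLong comparison** of paired AUCs uses the placement-value
  variance/covariance estimator (via pROC), two-sided normal p-value,
  no continuity correction; the variance is checked against a
  2000-resample bootstrap in tests. Degenerate placements yield an `NA`
  z, reported as such.
* **PLS-DA permutation validation**: labels are coded 0/1 and a
  PLS regression (5 components) is fitted. R²Y is the in-fit fraction
  of label variance explained; Q²Y its cross-validated counterpart
  (7-fold by convention in chemometrics, scaling refit per fold).
  The permutation statistic is the *separation distance*: the distance
  between class centroids in the latent score space divided by the
  pooled within-class spread — a latent-space effect size. The null
  refits the model on label-permuted data;
  \(p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\}) / (B + 1)\), so the
  smallest attainable p at B = 999 is 1/1000. An accuracy-based
  statistic would also be defensible; the centroid statistic was chosen
  because it is cheap, monotone in class separation, and does not
  depend on a secondary classifier.

# Numerical and degenerate-input conventions

* Exact confidence ties (0.5) go to control; a score exactly at the
  cutoff goes to control (strict `>`).
* Constant (zero-variance) features are dropped at the filter stage;
  scaling refuses them otherwise.
* A feature with no observed values aborts imputation (it should have
  been filtered).
* Members that fail to train abort the ensemble fit; the ensemble never
  silently shrinks.
* All randomness (cohorts, folds, permutations, stochastic learners)
  descends from integer seeds through fixed sub-stream derivation; two
  runs with the same configuration are byte-identical on disk.

# Problem sizes used by the test suite

The packaged simulations are sized for a laptop-class single core: the
full-scale demonstration uses the 120-sample training and 1430-sample
screening cohorts at 293 peaks; the null-calibration study uses 50
cohorts of 40 samples × 15 peaks at B = 99 permutations; parameter
recovery uses 10 replicates of 300 training / 1000 screening samples at
30 peaks. These sizes make the whole suite run in a few minutes while
keeping every statistical check adequately powered; all of them are
ordinary function arguments, so larger studies are one configuration
away.

# Known limitations

* Synthetic cohorts are independent-feature and log-normal; real GC-MS
  intensity tables have correlated blocks, batch structure, and
  heavier-tailed noise. Conclusions about the pipeline transfer;
  conclusions about absolute screening performance do not.
* The ensemble is a fixed weighted vote — no stacking, no calibration
  of the combined probability.
* The per-model confidence is the predicted-class probability. An
  alternative reading (always the EC-class probability) changes only
  the sign bookkeeping of the score; the classifications are identical
  under the weighted-probability rule. The package implements the
  predicted-class reading.
* Q²Y and R²Y depend on component count and fold count; defaults
  (5 components, 7 folds) follow chemometrics convention and are
  configurable.

# A worked run

```{r demo}
library(emlscreen)

cfg <- run_config(seed = 1)
art <- run_screening_study(cfg, out_dir = "results")
print(art)
```

The printed object reports the member weights, the ensemble's held-out
training accuracy, the screening confusion counts with all seven
indices, the EC-EML score AUC with the Youden cutoff, and the PLS-DA
permutation validation — the same quantities written to
`results/report.csv`, `results/scores.csv` and `results/validation.json`.
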