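---
title: "Testing feature importance in black-box models by permutation and cross-fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing feature importance in black-box models by permutation and cross-fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Flexible learners -- deep neural networks, random forests, kernel support
vector machines -- predict well on biomedical tabular data but say nothing
about which inputs matter.  For biomarker discovery the question is not only
*how well* a model predicts but *which features carry signal*, with an
honest error rate attached.  Ranking heuristics (impurity importances,
surrogate explainers) provide no test; the classical random-forest
permutation importance provides a standard error but, as its nulls are
evaluated on the same data the trees were grown on, its type-I error is
inflated -- roughly doubled in our simulations, and far worse when null
features are correlated with causal ones.

`permfit` implements a model-agnostic permutation importance *test*.  For a
feature $X_j$ define its importance as the expected increase in prediction
loss when $X_j$ is replaced by an independent copy from its marginal
distribution:

$$ M_j = E\left[\{\mu(X) - \mu(X^{(j)})\}^2\right], $$

where $\mu(x) = E(Y \mid X = x)$ and $X^{(j)}$ equals $X$ with the $j$-th
coordinate resampled.  $M_j = 0$ exactly when $\mu$ does not depend on
$X_j$ (absent redundant features).  Under a linear model
$\mu(X) = X\beta + \beta_0$ the score reduces to
$M_j = 2\beta_j^2\,\mathrm{Var}(X_j)$ -- the squared standardized
coefficient up to a constant -- which is what our test-suite oracles check
against.

## The estimator

Given a fitted approximation $\hat\mu$ and held-out samples
$(Y_i, X_{i\cdot})$, $i = 1, \dots, N_V$, shuffle the observed column $j$
without replacement and average the per-sample loss differences:

$$ \hat M_j^{(P)} = \frac{1}{N_V} \sum_{i=1}^{N_V}
   \left[\{Y_i - \hat\mu(X^{(j)}_{i\cdot})\}^2
       - \{Y_i - \hat\mu(X_{i\cdot})\}^2\right]. $$

With the *true* $\mu$ plugged in, the permuted copy is one draw from the
empirical marginal, and the score is unbiased for $\frac{N-1}{N} M_j$ (a
finite-sample factor the tests verify by brute-force enumeration against
Monte-Carlo simulation).  The per-sample contributions are i.i.d. up to the
shared permutation, so the variance of the mean is estimated by their
empirical second central moment divided by $N_V$, yielding a one-sided Z
test of $H_0: M_j \le 0$.

Two protocols evaluate the score on data the model never saw:

* **Single split** (default for simulations): fit on 80% of the samples,
  score on the remaining 20%.
* **K-fold cross-fitting** (default for data analyses, `K = 5`): fit
  $\hat\mu_k$ on the complement of fold $V_k$, score fold $V_k$, pool all
  $N$ contributions.  Every sample contributes exactly once per feature,
  and the reported estimate and variance are exact functions of the stored
  contribution matrix (asserted to $10^{-12}$ in the tests).

Why not score the training data?  An overfitted $\hat\mu$ tracks the
realized noise, so breaking the feature-outcome alignment by permutation
increases the loss even for null features: the plug-in estimator has a
positive bias under the null.  Cross-fitting removes that bias; the
baseline that scores in-sample (`vanilla_rf_importance()`) is kept
precisely to demonstrate it.

For binary outcomes $\mu(X) = P(Y = 1 \mid X)$ and squared error is
replaced by the increase in binomial deviance:

$$ M_j = E\left[Y \log\frac{\mu(X)}{\mu(X^{(j)})} +
   (1 - Y)\log\frac{1 - \mu(X)}{1 - \mu(X^{(j)})}\right], $$

with predicted probabilities clipped to $[10^{-6}, 1 - 10^{-6}]$ before
any logarithm, because backends may emit exact 0/1.

### Degenerate cases and numerical conventions

* A predictor that ignores feature $j$ yields contributions that are
  identically zero; the estimate and variance are exact zeros and the
  p-value is 1.
* Zero standard error with positive importance cannot arise from
  nondegenerate data; it returns $p = 0$ with a warning rather than 0/0.
* The number of permuted copies per feature defaults to `n_perm = 1`,
  matching the estimator above; larger values average the contributions
  over independent permutations before the variance is formed, trading
  compute for a little extra stability.
* Multiplicity is handled by Benjamini-Hochberg adjustment (`q_value`);
  the procedure is recorded in the output metadata because the choice is
  a package default, not something forced by the method.
* One master seed fans out to named substreams (split/folds, backend
  fits, per-feature permutations) via `derive_seed()`, so any stage can
  be reproduced in isolation.  In K-fold mode the permutation is drawn
  independently within each fold; a single global permutation would be an
  equally valid reading of the estimator, but per-fold draws keep fold
  computations independent and make no difference asymptotically.

### Feature groups

Permuting one column of a one-hot block would create impossible encodings
and tests the dummy, not the variable.  `feature_groups` permutes a block
of columns with a single row permutation, so an encoded categorical
feature (nationality, say) is tested as one unit.

## Learner backends

The backends exist so the package is self-contained; the test is
indifferent to where $\hat\mu$ comes from, and `new_predictor()` wraps any
external model.

* **Bagged DNN** (`fit_bagged_dnn()`): 100 feed-forward networks with
  hidden layers 50/40/30/20 (rectified linear), L2 penalty
  $\lambda = 10^{-4}$, mini-batches of 50, trained by Adam.  Each member
  fits a bootstrap resample and is scored on its out-of-bag samples; the
  best half (`keep_fraction = 0.5`) forms the ensemble -- bagged networks
  occasionally converge poorly, and dropping the worst members is cheaper
  than diagnosing them.  The learning-rate schedule (initial 0.03,
  multiplied by 0.995 per epoch, at most 100 epochs, early stop after 10
  stale epochs on a 10% member holdout) is a package choice: individual
  members deliberately overfit (training loss near zero) and the ensemble
  mean plus out-of-bag selection supply the regularization.
* **Random forest** (`fit_rf()`): 1000 CART trees on bootstrap resamples,
  `mtry = p/3` (regression) or $\sqrt p$ (classification), node size 5/1,
  best split by the sum-of-squares criterion (equivalent to Gini for 0/1
  outcomes), midpoint thresholds, no improvement threshold -- the best
  candidate split is always taken, as in classical forests.
  Classification forests predict the fraction of tree votes.
* **RBF SVM** (`fit_svm()`): epsilon-regression or C-classification
  solved by sequential minimal optimization with maximal-violating-pair
  selection; cost and kernel width chosen on a $\log_2$ grid
  ($2^{-3}..2^7 \times 2^{-7}..2^3$, step 2) by fivefold cross-validated
  loss.  Binary probabilities come from a sigmoid (Platt) calibration
  fitted on the training fold, since the deviance score needs
  probabilities, not margins.
* **Baseline** (`vanilla_rf_importance()`): Breiman's per-tree
  out-of-bag permutation importance -- for each tree the increase in OOB
  error after permuting a feature within the OOB set, averaged over
  trees, with the tree-wise standard deviation over $\sqrt{\#trees}$ as
  standard error.

DNN and SVM inputs are standardized with training-fold statistics only
(continuous outcomes likewise); forests see raw features.  Features must
arrive numeric and complete: imputation policy belongs to the caller (for
microbiome-style applications, median imputation before loading is the
documented convention).

## The simulated world

`generate_continuous()` / `generate_binary()` reproduce a block-correlated
Gaussian design: $p = 100$ features in blocks of $p_0 = 10$, unit
variances, within-block correlation $\rho \in \{0, 0.2, 0.5, 0.8\}$, zero
across blocks, sampled through the (lower-triangular, feature-major)
Cholesky factor so a seed pins the exact layout.  The first feature of
each of the first five blocks carries signal:

$$ Y = X_1 + 2\log\big(1 + 2X_{11}^2 + (X_{21} + 1)^2\big)
     + X_{31}X_{41} + \epsilon,\qquad \epsilon \sim N(0, 1), $$

mixing a linear effect, a strong nonlinearity and a pure interaction.  The
binary design passes $4X_1 + 8\log(\cdot) + 4X_{31}X_{41} - 11$ through
the logistic function (the offset balances the event rate near 1/2).
Null features split into $S_0$ (sharing a block with a causal feature;
correlated nulls) and $S_1$ (later blocks; independent nulls) -- the
distinction that separates an honest test from the baseline, whose $S_0$
false-positive rate exceeds 80% at $\rho = 0.8$.

What the generator does *not* emulate: heavy tails, skewness,
heteroscedastic noise, compositional constraints, missingness.  A green
calibration test therefore establishes correctness of the inference under
a Gaussian world with known truth, not robustness to real-data pathology.

`replicate_scenario()` loops generate/fit/test/select/refit, records the
replicate-by-feature p-value matrix, detection rates per causal feature,
pooled rejection rates over $S_0$ and $S_1$ (pooling over replicates and
features is the primary summary; feature-wise rates are also returned),
and -- when `refit = TRUE` -- prediction metrics of the full against the
selected model on an independent test set, with an empty selection falling
back to the full model (flagged).  Detection uses $\alpha = 0.05$; refit
selection uses $\alpha = 0.1$.  The full study uses 100 replicates and a
10,000-sample test set; the shipped acceptance runs use 20-30 replicates
and are documented as scaled down.

## Known limitations

* The test is marginal: a feature whose effect is entirely absorbed by a
  correlated partner can mask or be masked; the method controls false
  positives under correlation but cannot resolve credit between near
  duplicates.
* Importance is measured on the loss scale of the fitted learner; a
  misspecified or badly underfitted learner yields low power (the forest
  backend barely sees the $X_{31}X_{41}$ interaction, by the nature of
  axis-aligned splits).
* The SMO solver stores the full kernel matrix; the SVM backend is meant
  for $N$ up to a few thousand.
* Single-threaded throughout; reproducibility is tied to R's RNG stream.
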