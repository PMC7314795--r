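---
title: "Harmonizing multicenter radiomic features: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing multicenter radiomic features: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radharmony)
```

## The problem

Radiomic features — quantitative morphology, intensity and texture
descriptors extracted from medical images — are notoriously sensitive to
the scanner model, acquisition protocol and reconstruction settings.
When cohorts from several centers are pooled, this "center effect" (the
imaging analogue of the batch effect in gene-expression arrays) can
dwarf the biological signal: feature distributions differ systematically
by center, multivariate summaries separate by site rather than by
disease, and predictive models trained at one center transfer poorly to
another. radharmony implements a family of empirical-Bayes location-scale
harmonization methods that remove these effects from a feature table
while preserving the biology (and optionally protected covariates),
together with the tooling needed to use and evaluate them when center
labels are known, unknown, or unreliable.

## The location-scale model

For sample $j$ of batch $i$ and feature $g$, the observed value is
modelled as

$$Y_{ijg} = \alpha_g + X_{ij}\,\beta_g +
  \sigma_g\,(\gamma_{ig} + \delta_{ig}\,\varepsilon_{ijg}),
  \qquad \varepsilon_{ijg} \sim N(0, 1),$$

where $\alpha_g$ and $\sigma_g$ are the feature's biological location
and scale, $X\beta_g$ an optional covariate effect to be preserved, and
$\gamma_{ig}$ (additive) and $\delta_{ig}$ (multiplicative) the batch
effects to be removed. Estimation proceeds in three steps:

1. **Standardization.** Ordinary least squares on the batch-indicator
   (+ covariate) design gives $\hat\alpha_g$, $\hat\beta_g$,
   $\hat\sigma_g$; the standardized data
   $Z = (Y - \hat\alpha - X\hat\beta)/\hat\sigma$ are assumed
   $Z_{ijg} \sim N(\gamma_{ig}, \delta^2_{ig})$.
2. **Empirical-Bayes shrinkage.** Raw per-batch effects
   ($\hat\gamma_{ig}$ = within-batch mean of $Z$, $\hat\delta^2_{ig}$ =
   within-batch variance) are stabilized by pooling across features: a
   Normal prior on $\gamma$ and an Inverse-Gamma prior on $\delta^2$,
   per batch, with hyperparameters estimated by the method of moments.
3. **Adjustment.** $Y^* = \dfrac{\hat\sigma_g}{\hat\delta^*_{ig}}
   (Z_{ijg} - \hat\gamma^*_{ig}) + \hat\alpha_g + X\hat\beta_g$.

### The four variants

* **ComBat** (`variant = "combat"`): grand-mode standardization; all
  batches are recentered on the pooled location and scale. The pooled
  location is the batch-size-weighted mean of per-batch OLS intercepts
  and the pooled scale the mean squared residual over *all* samples
  (population $1/n$ divisor), matching the widely used reference
  implementation, against which the package is pinned to $10^{-6}$
  agreement in its tests.
* **M-ComBat** (`"m-combat"`): each batch is standardized by its *own*
  mean and spread (so $\hat\gamma_{ig} \equiv 0$,
  $\hat\delta^2_{ig} \equiv 1$ by construction) and mapped onto the
  moments of a chosen *reference* batch. This keeps harmonized values on
  a real center's scale — no impossible values such as negative volumes
  from recentering on an abstract grand mean — and leaves the reference
  batch itself unchanged. The default reference is the largest batch
  (most samples, most stable moments).
* **B-ComBat / BM-ComBat** (`"b-combat"`, `"bm-combat"`): the same two
  geometries with every coefficient replaced by its Monte-Carlo average
  over `n_boot` stratified bootstrap refits (default 1000), trading a
  little computation for estimator stability on small batches.

### Conventions worth knowing

These choices are deliberate, documented, and pinned by tests:

* **Variance divisors.** Grand-mode pooled scale: population $1/n$;
  within-batch spread $\hat\delta^2$: sample $n_i - 1$; batchwise
  (M-ComBat) per-batch scale: sample $n_i - 1$, which makes
  $\hat\delta^2 \equiv 1$ exact and reference preservation bit-exact.
  A side effect of the grand-mode mismatch (inherited from the reference
  implementation): re-harmonizing already-harmonized data contracts the
  scale by exactly $\sqrt{(n - I)/n}$ per pass (locations are stable at
  $10^{-10}$), and single-batch grand-mode input contracts deviations by
  $\sqrt{(n-1)/n}$; both factors are asserted exactly in the tests.
* **Bootstrap averaging.** Coefficients are averaged on the
  standard-deviation scale (the scale on which $\hat\sigma/\hat\delta^*$
  enters the adjustment), and the averaged coefficients are applied
  inside the standard adjustment form, which reduces to the point fit as
  the resampling noise vanishes. A literal raw-scale application of the
  averaged coefficients is available behind
  `bootstrap_form = "literal"` for comparison.
* **Bootstrap scheme.** Default is stratified case resampling within
  batch (each batch keeps its size); `bootstrap_mode = "parametric"`
  draws model-based resamples from the fitted location-scale model
  instead. Resamples that lose all spread on some feature are redrawn
  and counted; more than 50% redraws aborts with advice.
* **Degenerate inputs.** Features with zero within-batch variance
  break the scale model and are refused, or dropped with a message under
  `drop_degenerate = TRUE`. If all features share identical raw effects
  the across-feature prior collapses; the shrinkage then falls back to
  the exact point-mass posterior (this is also what makes M-ComBat's
  degenerate $\hat\gamma \equiv 0$, $\hat\delta^2 \equiv 1$ case exact
  rather than an error).

## Empirical-Bayes priors

Two shrinkage modes are provided (plus `prior = "none"`, which passes
raw estimates through unchanged and is the closed-form oracle used
throughout the test suite):

* **Parametric** (`"parametric"`): the conjugate Normal/Inverse-Gamma
  posterior means, solved by the classic fixed-point iteration;
  convergence at relative coefficient change $\le 10^{-4}$, error with
  diagnostics after 100 iterations.
* **Nonparametric** (`"nonparametric"`, the default, as used in the
  study this package operationalizes): each feature's posterior effect
  is the likelihood-weighted average of the *other* features' raw
  estimates. The weights depend on the batch data only through $n$,
  $\sum z$ and $\sum z^2$, so the package evaluates them from sufficient
  statistics in log space — algebraically identical to the naive
  per-sample product (asserted in tests against that oracle) but immune
  to the underflow that the naive product suffers for large batches.

A practical caveat, quantified in the tests: nonparametric shrinkage is
a *local averaging* over features with similar raw effects. When
injected effects are widely dispersed and features are independent, the
features at the edge of the effect distribution keep a one-sided
residual of up to a few tenths of a pooled SD in their batch means after
grand-mode harmonization (the reference implementation behaves
identically). This residual stays below ANOVA detectability — the
criterion that matters for pooling — and vanishes for `prior = "none"`
and for the M variants, whose alignment is exact by construction. The
parametric prior keeps residuals within 0.05 pooled-SD.

## Discovering harmonization labels

When acquisition settings vary so much that center labels are unusable,
`silhouette_select_k()` discovers labels: agglomerative clustering
(Ward's minimum-variance linkage by default — consistent with the
Euclidean metric; average/complete available) on per-feature z-scored
data, with the number of clusters chosen by maximum mean silhouette
width $s = (b - a)/\max(a, b)$ over a candidate range (default
$2..\min(10, n-1)$; ties break toward smaller $k$, since fewer labels
leave more samples per batch for the harmonization fit). Features are
z-scored before distances because radiomic features span wildly
different units; the tree and cut are fully deterministic.
`outcome_balance_check()` guards against the failure mode where clusters
encode the clinical endpoint instead of the center effect: it compares
per-cluster event rates with a proportion test and flags partitions with
significantly uneven rates.

## Evaluation battery

`evaluate_harmonization()` bundles the quality measures:

* per-feature one-way equal-variance ANOVA across labels with the
  fraction significant at $\alpha$ (default 0.01, raw p-values);
* an aggregate coefficient of variation: the sum over features of
  $|sd_g / \mathrm{mean}_g| \times 100$. This is a defined, documented
  dispersion statistic of the right order of magnitude for feature
  tables of this size; note it is dominated by features whose mean sits
  near zero, so small location changes can swing it — it should be read
  comparatively (untransformed vs harmonized), not as a precise figure
  of merit;
* top-2 correlation PCA (z-scored features; signs fixed so the
  largest-magnitude loading is positive) for visual inspection;
* balanced accuracy ($(\mathrm{sens} + \mathrm{spec})/2$) and the
  Matthews correlation coefficient (0 by convention when a confusion
  marginal is empty) for scoring classifiers under class imbalance.

## Synthetic multicenter cohorts

`generate_synthetic()` draws data from exactly the location-scale model
above, with known ground truth returned alongside: biological
$\alpha_g \sim U(5, 50)$, $\sigma_g \sim U(0.5, 5)$, batch shifts with
magnitude $U(1.5, 2.5)\,\sigma_g$, scale distortions
$\delta \sim U(0.8, 1.2)$, three batches of 60/50/40 samples, 150
features, and a binary outcome with 25% event rate driven by 5
informative features through a logistic model on the *pre-batch-effect*
biology (so outcome and batch are independent by construction — the
assumption the label-discovery check verifies). Shift signs are drawn
per feature from the non-constant patterns across batches: a shift
common to every batch is absorbed into $\alpha_g$ and is not an
identifiable batch effect, so injected effects always differ somewhere
between batches. `lacc_like_preset()` (3 centers of 119/50/28, 173
features, 34% events) and `lalc_like_preset()` (2 clusters of 60/38,
15% events) pin the cohort shapes of the two published studies this
package mirrors.

What the generator does *not* emulate: realistic (heavy-tailed,
discretization-dependent) texture-feature marginals, and the strong
inter-feature correlation of real radiomics (an optional equicorrelation
is available but off by default). Passing tests on this generator
demonstrates correct estimation under the model's own assumptions; real
features violate normality to a degree the tests cannot certify.
Because real radiomic features are highly correlated while the generator
defaults to independent ones, the nonparametric-shrinkage caveat above
is, if anything, harsher here than in practice.

## The imbalance-aware benchmark

`run_benchmark()` reproduces the downstream comparison design: the whole
cohort is harmonized (the transform never sees the outcome), the
training set is the reference batch and the test set the remaining
batches, the training fold is balanced by SMOTE (synthetic minority
samples interpolated toward one of 5 nearest minority neighbors; the
test fold is never touched, asserted by test), and three pipelines are
scored: logistic regression on LASSO-selected features (10-fold CV
penalty), and random forest / linear-kernel SVM with embedded feature
selection (importance or single-feature CV-accuracy ranking averaged
over stratified bootstrap refits, then forward selection over the
ranking prefix to the global minimum of out-of-bag balanced error). The
SVM ranking criterion is an interpretation of a leave-one-out-style
single-feature score; `fs_config(svm_rank_folds = Inf)` gives the exact
leave-one-out reading, with k-fold the tractable default. A strict
train-only harmonization mode exists behind
`benchmark_config(strict_train_only = TRUE)`; with a batch-defined
split it documents the method's core limitation — a fit that never saw
the test batches cannot transform them, so their rows pass through
untransformed.

## Problem sizes and runtimes

The test suite and the acceptance script run the method at deliberately
modest sizes chosen to exercise every property while keeping the full
battery in the minutes range: engine fixtures of 37-180 samples and
15-150 features; parameter recovery at $n_i = 50$, $G = 100$ over 10-20
seeds with $B = 200$; the benchmark grid on the 197-sample preset over
5-10 seeds with $B = 100$ and reduced forest/selection knobs
(`fs_config(n_trees = 100, n_importance = 10, n_val = 5, max_subset =
10)`). The package defaults ($B = 1000$, `fs_config()` as documented)
are the recommended analysis settings.

## Known limitations

* A fitted model applies only to batches seen at fit time; there is no
  supported transform for a single new patient from an unseen center
  (`predict()` refuses unseen labels). Adding a center means re-fitting
  on the combined cohort.
* Grand-mode nonparametric shrinkage leaves the edge-feature residuals
  described above; use the M variants (exact alignment) or the
  parametric prior when exact batch-mean alignment matters more than
  robustness to non-normal effects.
* The aggregate COV is unstable for near-zero-mean features; in
  particular it cannot reliably rank the bootstrap variants against
  their point counterparts, whose outputs differ by far less than the
  statistic's sensitivity to mean placement. The bootstrap variants'
  benefit shows instead in parameter-recovery error, which is what the
  acceptance battery measures.
* Harmonization assumes comparable case mix across batches; confounding
  between batch and biology is detected (`outcome_balance_check`) but
  not corrected.
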