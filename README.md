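# radharmony

Batch-effect ("center-effect") harmonization of multicenter radiomic
feature tables with the empirical-Bayes ComBat family, for researchers
pooling quantitative imaging features — morphology, intensity and
texture descriptors — across scanners, protocols or sites before
statistical analysis or predictive modelling.

Radiomic features are highly sensitive to acquisition and
reconstruction settings, so feature distributions differ systematically
by center and models trained at one site transfer poorly to another.
ComBat models the observed value of feature *g* for sample *j* of batch
*i* as a location–scale perturbation of the biology,

  Y_ijg = α_g + X_ij β_g + σ_g (γ_ig + δ_ig ε_ijg),  ε ~ N(0, 1),

standardizes with OLS estimates of α_g, β_g, σ_g, stabilizes the raw
per-batch effects γ̂_ig (within-batch means) and δ̂²_ig (within-batch
variances) by empirical-Bayes shrinkage with method-of-moments priors
(Normal for γ, Inverse-Gamma for δ²; parametric or nonparametric), and
adjusts:

  Y\*_ijg = (σ̂_g / δ̂\*_ig) (Z_ijg − γ̂\*_ig) + α̂_g + X β̂_g.

Four variants are provided through one fitting function, `harmonize()`:

| variant | what it does |
|---|---|
| `combat` | classic ComBat: recenter all batches on the pooled location/scale |
| `m-combat` | map every batch onto a chosen *reference* batch's moments; the reference itself is unchanged |
| `b-combat` | ComBat with all coefficients Monte-Carlo-averaged over stratified bootstrap refits |
| `bm-combat` | both modifications combined |

Around the engine: silhouette-scored hierarchical clustering to
*discover* harmonization labels when settings are too heterogeneous to
label manually (with an outcome-confounding check), an evaluation
battery (per-feature ANOVA across labels, aggregate COV, top-2 PCA,
balanced accuracy, Matthews correlation), a synthetic multicenter
generator with known ground-truth batch effects, and an imbalance-aware
ML benchmark harness (SMOTE + LASSO-logistic / random-forest / SVM
pipelines with embedded feature selection).

## Worked example

Simulate a three-center cohort shaped like a 197-patient cervical-cancer
study (119/50/28 patients, 173 features, 34% event rate), harmonize it
onto the largest center with BM-ComBat, and summarize:

```r
library(radharmony)

d <- generate_synthetic(lacc_like_preset(seed = 1))
fit <- harmonize(d$values, d$batch, variant = "bm-combat",
                 reference = "batch1", n_boot = 200, seed = 1)
summary(fit)
#> ComBat harmonization fit (variant: bm-combat, prior: nonparametric)
#>   197 samples x 173 features, 3 batches (batch1: 119, batch2: 50, batch3: 28)
#>   reference batch: batch1
#>   bootstrap: B = 200 (case resampling, seed 1, 0 redraws)
#>   ANOVA across batches (alpha = 0.01): 173/173 significant before, 0 after
#>   aggregate COV: 5022.2 before, 3199.4 after
#>   prior: degenerate by construction (batchwise effects are exactly 0/1)
```

Before harmonization every one of the 173 features differed
significantly across centers (p < 0.01); afterwards none do, the
aggregate dispersion drops, and — because `bm-combat` is
reference-anchored — the harmonized table sits on batch1's original
scale rather than an abstract grand mean. `fitted(fit)` returns the
harmonized matrix, `coef(fit)` the per-batch effect estimates,
`predict(fit, newdata, batch = ...)` re-applies the stored transform to
rows from batches seen at fit time, and `plot(fit)` draws before/after
PCA panels. With classic `combat` the same summary also prints the
fitted prior hyperparameters per batch, e.g.
`batch1: gamma_bar = -0.0739, t2 = 1.44, IG(a = 52, b = 51.1)`.

When center labels are unreliable, discover them first:

```r
cs <- silhouette_select_k(d$values, k_range = 2:6, outcome = d$outcome)
cs
#> Silhouette-selected clustering
#>   mean silhouette by k: 2: 0.475, 3: 0.590, 4: 0.239, 5: 0.238, 6: 0.237
#>   chosen k = 3 (cluster sizes: 119, 50, 28)
#>   event rate per cluster: 1: 45/119 (37.8%), 2: 11/50 (22.0%), 3: 9/28 (32.1%)
#>   proportion test p = 0.136
```

The three injected centers are recovered exactly, and the per-cluster
event rates are statistically indistinguishable — evidence the clusters
reflect acquisition differences, not outcome.

A thin command-line front end over the same functions ships in
`inst/cli/radharmony` (`harmonize`, `discover-labels`, `evaluate`,
`simulate`, `benchmark` subcommands).

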