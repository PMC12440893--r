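# settlehealth

Tools for studying how the human settlement environment (HSE) relates to
population health in province-year panel data, the way recent provincial
analyses in China do it: a composite **Health Level Index (HLI)** is built
from four health indicators by the entropy-weight TOPSIS method, the
relationship between 19 settlement-environment indicators and the index is
modelled with gradient-boosted trees benchmarked against five alternative
regression families, and the fitted model is interpreted through additive
Shapley attributions, LOWESS zero-crossing threshold estimates with
bootstrap confidence intervals, and two-way partial dependence surfaces.

The package is aimed at biostatisticians and spatial-epidemiology
researchers who want this analysis chain as tested, seeded, reusable
functions rather than a one-off script — including a synthetic panel
generator with *known* planted effects, so every stage can be validated
against ground truth before it ever touches real data.

## The methods in brief

**Composite index (entropy-weight TOPSIS).** With m pooled province-year
samples and 4 direction-tagged indicators, each column is min–max
normalised so larger is always better (negative-direction indicators are
reflected). Column proportions r_ij = x'_ij / Σ_i x'_ij give the Shannon
entropy

    e_j = −(1/ln m) Σ_i r_ij ln r_ij        (0·ln 0 ≡ 0)

and weights w_j = (1 − e_j) / Σ_k (1 − e_k): an indicator's weight grows
with its cross-sample information content. TOPSIS then scores each sample
by relative closeness to the column-wise ideal point in the weighted
space,

    HLI_i = D_i− / (D_i+ + D_i−)  ∈ [0, 1],

with D_i± the Euclidean distances to the ideal / anti-ideal rows.

**Benchmark protocol.** Rows are split 8:2 at a fixed seed (2025),
resampling at the province-year level; models are compared on R², RMSE
and MAE (computed from their definitions) plus 5-fold cross-validation,
with optional random hyperparameter search. The boosted families run at
the reproduction preset: learning rate 0.05, 200 estimators, depth 3.

**Explanation.** Shapley attributions satisfy local accuracy,
ŷ_i = φ₀ + Σ_j φ_ij, enforced row-wise at every call (exact TreeSHAP for
the boosted models, exactly-additive permutation sampling for the rest).
Mean |φ| per feature gives the importance ranking and percentage shares.
For each top feature, a locally linear LOWESS curve (tricube weights,
span 0.3) is fitted to the (feature, attribution) scatter; the
**threshold** is the feature value where the curve crosses zero, with a
95% percentile bootstrap interval, and plateaus are detected from the
curve's terminal slopes. Two-way partial dependence surfaces expose
interaction structure.

## Worked example

Generate the default synthetic study conditions — a 31-province × 11-year
panel with the 19 settlement indicators at realistic provincial ranges
and planted sign-changing effects on the six key features — then run the
full chain:

```r
library(settlehealth)

spec <- synthetic_spec_default(seed = 1)
gp   <- generate_panel(spec)

# composite index from the four generated health indicators
ind <- generate_health_indicators(gp, indicator_noise = 0.01)
hli <- build_hli(ind)
hli
#> Entropy-TOPSIS composite index over 341 pooled samples
#> Entropy weights:
#>    incidence_ab    mortality_ab human_mortality life_expectancy
#>          0.2497          0.2474          0.2583          0.2446
#> Index (HLI) range: [0, 1]

# benchmark six regression families on the planted-effect outcome
fml   <- as.formula(paste("HLI ~", paste(names(spec$feature_ranges), collapse = " + ")))
bench <- run_benchmark(gp$panel, fml, k = 5)
bench
#> Benchmark of 6 model families (train 272 / test 69, seed 2025)
#>         family r2_train r2_test rmse_train rmse_test mae_train mae_test cv_r2
#>           gbdt    0.983   0.836      0.012     0.040     0.009    0.031 0.770
#>        xgboost    0.980   0.832      0.013     0.040     0.010    0.031 0.776
#>      hist_gbdt    0.979   0.829      0.013     0.041     0.010    0.031 0.774
#>       adaboost    0.857   0.740      0.034     0.050     0.029    0.038 0.650
#>          lasso    0.753   0.730      0.044     0.051     0.035    0.042 0.712
#>  random_forest    0.947   0.722      0.020     0.052     0.016    0.040 0.651

# attribution, importance shares, and a threshold with bootstrap CI
shap <- compute_attributions(bench$models$xgboost, gp$panel)
head(importance_shares(shap), 6)
#>   feature mean_abs_phi share rank
#> 1    NMIB      0.04340 29.26    1
#> 2    MPPR      0.02486 16.76    2
#> 3      UR      0.02323 15.66    3
#> 4    RAPC      0.01842 12.41    4
#> 5      PD      0.01547 10.43    5
#> 6    UGPR      0.00906  6.11    6

bootstrap_threshold(attribution_scatter(shap, "NMIB"),
                    span = 0.3, n_boot = 1000, seed = 1, recenter = TRUE)
#> Threshold 58.47 (95% CI 57.44-59.69), direction +-, 1000 resamples
```

Reading the output: the six planted features head the importance ranking
(hospital-bed density NMIB largest, 29% of total attribution); the NMIB
attribution curve falls through zero near 58 beds per 10,000 — close to
the planted sign change at 60.21 — meaning higher bed density is
associated with *better* predicted health below the threshold and worse
above it. The tree ensembles beat the Lasso baseline out of sample, as
expected when the planted effects are nonlinear.

The same chain runs end to end from one configuration object (or YAML
file; see `inst/extdata/example_config.yaml` and
`inst/scripts/run_pipeline.R` for the shell entry point):

```r
cfg <- pipeline_config(directions = health_indicator_directions(),
                       output_dir = "results/run1")
bundle <- run_pipeline(cfg, panel = ind)
```

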