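# feedrsf — resource selection at carnivore feeding sites

`feedrsf` is an R package for analyzing **where large carnivores kill and
consume their prey**, built for GPS-collared predators (the motivating
system is mountain lions preying on mule deer along an urban–wildland
gradient) and for anyone who needs a tested, end-to-end
use–availability pipeline:

* **Cluster detection** — feeding sites are inferred from spatio-temporal
  clusters of GPS fixes: ≥ 2 night fixes within ≤ 50 m of each other
  spanning ≥ 24 h (single-linkage chaining, all parameters configurable).
* **Availability** — per animal-year adaptive local convex hull (a-LoCoH)
  home ranges with the adaptive parameter `a` set to the maximum pairwise
  distance between fixes; availability is a systematic 150 m lattice over
  the range (≈ 44 pixels/km²).
* **Covariates** — exact Euclidean distance transforms of habitat and
  land-use rasters (distance to chaparral, riparian woodland, water,
  trails, developed and altered-open areas, …), plus elevation and Horn
  slope, all read at the 30 m pixel.
* **The selection model** — a binomial GLMM of used (1) vs available (0)
  pixels with random intercepts for individual and year-in-individual,
  Gelman 2-SD standardization, sex × covariate interactions, AIC model
  selection (ΔAIC > 5 = strong support), 95/90/85 % Wald intervals, and
  k-fold cross-validation scored by the Spearman correlation between
  probability-bin rank and held-out feeding-site frequency.
* **Functional responses** — per-animal selection proportions,
  P = mean used distance / (mean used + mean available), regressed on
  availability with beta regression (probit link) and a penalized spline
  smooth whose estimated degrees of freedom (edf) decide linear vs
  nonlinear.
* **Synthetic data** — landscapes, tracks and feeding sites planted under
  known selection coefficients, so every stage is verifiable by parameter
  recovery.

The model, for pixel *i* of animal *j* in year *k*:

```
logit P(y_ijk = 1) = β0 + x_i'β + male_j · x_i'γ + b_j + b_jk,
b_j ~ N(0, σ²_id),  b_jk ~ N(0, σ²_yr)
```

For distance-based covariates **negative β means selection** (used sites
closer to the feature than available ones); for elevation and slope the
convention flips. Coefficients describe *relative* probability of use.

## Worked example

A synthetic six-animal study with known coefficients (females select
developed areas and avoid riparian woodland and high elevation; males
differ on riparian, water and developed — three true sex interactions):

```r
library(feedrsf)
cfg <- pipeline_config(
  n_animals = 6, days = 30, kills_per_animal = 12,
  landscape   = landscape_config(n_rows = 120, n_cols = 120),
  beta_true   = c(d_developed = -1, d_riparian = 0.7,
                  elevation = -0.9, slope = 0.25),
  sex_effects = c(d_riparian = -0.9, d_water = -0.7, d_developed = 0.8),
  seed = 42)
res <- run_pipeline(cfg, quiet = TRUE)
print(res)
#> Feeding-site RSF pipeline report
#>   1728 fixes -> 109 clusters -> 109 feeding sites; 6 home ranges
#>   table: 2373 rows; retained covariates: d_chaparral, d_riparian, d_upland, ...
#>   best model: reduced_interactions; CV r_s = 0.81
#>   functional response d_developed: chi-sq 0.00, P = 0.998, edf 1.0
#>   functional response d_altered_open: chi-sq 0.40, P = 0.574, edf 1.0

print(res$comparison)
#> Model comparison (AIC)
#>                  model npar   aic delta_aic
#> 1 reduced_interactions   17 879.1       0.0
#> 2                 null    3 890.5      11.4
#> 3     all_interactions   26 892.5      13.4
#> 4         main_effects   15 894.1      15.1
#> Best model strongly supported (runner-up delta > 5)

summary(res$fits[[res$report$best_model]])
#> ...
#> d_developed          -1.33 -2.41 -0.25 -2.24 -0.43    95%
#> elevation            -0.51 -0.92 -0.10 -0.86 -0.17    95%
#> d_developed:sex_male  1.99  0.85  3.12  1.04  2.94    95%
#> ...
#> AIC 879.1 (logLik -422.5), 109 used / 2264 available
```

Reading the output: the 109 detected clusters include the 72 planted
feeding sites plus incidental rest clusters; model selection recovers the
interaction structure (the reduced-interactions model wins by ΔAIC 11.4
and is strongly supported); the main effect for `d_developed` is negative
and significant — females fed closer to development than expected from
availability — while the positive `d_developed:sex_male` interaction says
males did so less; and 5-fold cross-validation puts the Spearman bin
correlation at 0.81, i.e. held-out feeding sites concentrate in
high-probability bins. Per-sex prediction maps are in `res$maps`, the
functional-response fits (here null, as simulated) in
`res$functional_responses`, and a JSON-serializable run report with every
decision and seed in `res$report`.

Individual stages are plain functions returning classed objects —
`detect_clusters()`, `alocoh()` / `estimate_home_ranges()`,
`distance_stack()`, `build_table()`, `standardize_gelman()`, `rsf_fit()`
(with `summary`, `coef`, `confint`, `predict`, `predict_map`),
`kfold_cv()`, `aggregate_animals()`, `fit_beta_fr()` (with `plot`) — so
any slice of the pipeline can be run on its own data: telemetry as CSV
(`read_telemetry()`), rasters as ESRI ASCII grids (`read_landscape()`),
metadata as CSV (`read_metadata()`).

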