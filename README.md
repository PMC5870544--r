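# benchdrift

Pre-analytical handling leaves fingerprints in plasma metabolomics data.
When whole blood sits before centrifugation, metabolism continues: lactate
and pyruvate rise, glucose falls, and the size of these changes depends on
the delay time (1–36 h) and storage temperature (4 °C vs 22 °C). benchdrift
is an R toolkit for dealing with this in NMR metabolite feature tables,
aimed at biobank-scale studies and at archived ("legacy") samples whose
handling metadata are missing. It provides:

* **Normalization** — probabilistic quotient normalization (PQN) of a
  samples × features table, with an external-reference mode for bridging
  batch effects;
* **Drift modeling** — per-subject fold-change profiles relative to the
  1 h reference state, filtering of features whose drift is irreproducible
  between subjects, hierarchical clustering of the reproducible profiles,
  and an anchored natural cubic spline drift function per cluster,
  `g_c(t)` with `g_c(1 h) = 1`;
* **Correction** — multiplicative normalization of intensities back to the
  1 h state, `x' = x / g_c(t)`, using recorded *or* predicted
  pre-centrifugation times;
* **Handling prediction** — random-forest classification of storage
  temperature and regression of delay time, with recursive unbiased
  variable selection inside repeated double cross-validation (rdCV) and
  permutation-based significance (empirical and parametric p-values);
* **Evaluation** — per-cluster and global CV accounting with Wilcoxon
  signed-rank significance of improvement, deviation-percentile surfaces,
  and Tukey-adjusted group comparisons of predicted times;
* **Simulation** — a fully seeded synthetic study generator with planted
  drift clusters, irreproducible features and complete ground truth.

Everything is tibble-in / tibble-out; fitted objects have `tidy()`,
`glance()` and `autoplot()` methods. A command-line wrapper with
subcommands (`simulate`, `normalize`, `fit-drift`, `correct`, `train-temp`,
`train-time`, `predict`, `evaluate`) lives at
`system.file("cli", "benchdrift.R", package = "benchdrift")`.

## Worked example

Simulate a small handling study (8 subjects, 120 features, both
temperatures), normalize, model drift at room temperature, and correct:

```r
library(benchdrift)
library(dplyr)

cfg <- sim_config(n_subjects = 8, n_features = 120, seed = 42)
sim <- simulate_handling_study(cfg)
pq  <- pqn_normalize(sim$table)

m22 <- filter(sim$meta, temperature_c == 22)
t22 <- filter(pq$normalized, sample_id %in% m22$sample_id)

model <- fit_drift_model(t22, m22)
model
#> <drift_model> 22 degC, 3 clusters, 94 modeled features, 26 excluded
#>   time points (h): 1, 3, 8, 24, 36; anchored at t = 1 h

corrected <- correct_drift(t22, model, times = m22)
report <- correction_report(t22, corrected, model = model, meta = m22)
report
#> <correction_report> 120 features, 3 clusters
#>   total mean CV: 0.145 -> 0.065 (metadata)

tidy(report)[, c("cluster_id", "n", "cv_original",
                 "cv_corrected_metadata", "stars_metadata")]
#> # A tibble: 3 × 5
#>   cluster_id     n cv_original cv_corrected_metadata stars_metadata
#>        <int> <int>       <dbl>                 <dbl> <chr>
#> 1          1    36      0.0491                0.0474 ***
#> 2          2    30      0.223                 0.0710 ***
#> 3          3    28      0.225                 0.0483 ***
```

Reading this: the drift model found one stable cluster (CV ≈ 5% before and
after — nothing to correct) and two drifting clusters whose
handling-induced variation (CV ≈ 22% over the 1–36 h design) collapses to
5–7% after correction, with the per-cluster Wilcoxon improvement test
significant at p < 0.001 (`***`). The 26 excluded features drifted
irreproducibly between subjects and pass through uncorrected.

For samples without metadata, train predictors and route the correction
through them:

```r
rcfg <- rdcv_config(n_rep = 5, n_outer = 6, seed = 7)
temp_model <- rdcv_fit(pq$normalized, factor(sim$meta$temperature_c),
                       rcfg, subjects = sim$meta$subject_id)
time_22 <- rdcv_fit(t22, m22$time_h, rcfg, subjects = m22$subject_id)
res <- correct_predicted(t22, temp_model,
                         time_models = list("22" = time_22),
                         drift_models = list("22" = model))
```

`rdcv_permutation()` assesses significance of any fitted model against
outcome-permuted refits.

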