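---
title: "Modeling and correcting pre-centrifugation drift in plasma metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and correcting pre-centrifugation drift in plasma metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benchdrift)
library(dplyr)
```

## The problem

Whole blood that sits before centrifugation keeps metabolizing. Energy
metabolism intermediates move first and fastest — lactate and pyruvate
accumulate, glucose is consumed — and the extent of these changes depends on
how long the tube sat (the pre-centrifugation delay) and at what temperature
(refrigerator vs room temperature). For biobanked plasma analyzed by NMR
this creates two distinct problems:

1. **Archived samples often lack handling metadata.** Can delay time and
   temperature be *predicted* from the measured feature table itself?
2. **Even when handling is documented, the drift biases the data.** Can the
   reproducible part of the drift be *modeled and removed*, restoring each
   sample towards a common reference state (1 h delay)?

benchdrift implements both: random-forest prediction of handling conditions
inside a repeated double cross-validation (rdCV) scheme with permutation
testing, and a cluster-based kinetic drift model used for multiplicative
correction. A synthetic study generator with complete ground truth supports
validation of every step.

## Data model

A *feature table* is a tibble with a `sample_id` column and one non-negative
numeric column per metabolite feature (peak heights at chemical shifts).
*Sample metadata* carries `sample_id`, `subject_id`, `time_h`
(pre-centrifugation delay in hours) and `temperature_c`. All user-facing
functions take these tibbles first and return tibbles or tidy-able objects,
so pipelines compose with the pipe.

## Probabilistic quotient normalization

Dilution-like sample-level intensity effects (and the peak-shape batch
effect between measurement batches) are removed first by PQN: for sample
$i$ with reference spectrum $r$,

$$ f_i = \operatorname{median}_{\,f:\, x_{if} > 0,\ r_f > 0}
   \left( x_{if} / r_f \right), \qquad x'_{if} = x_{if} / f_i . $$

The default reference is the feature-wise median over the input table. An
*external* reference vector lets a later batch be normalized against the
training batch's reference — the mechanism used to bridge batches before
external prediction. Quotients are computed only over features positive in
both sample and reference; a sample with no positive overlap is an error.
There is no total-area pre-normalization: PQN is applied as a single step.

## Drift modeling

For one storage temperature, `fit_drift_model()` chains four stages:

1. **Profiles** (`compute_drift_profiles()`). For each feature and subject,
   intensities are scaled by the subject's own sample at the reference time
   $t_{\mathrm{ref}} = 1$ h, giving fold-change kinetics free of
   between-person level differences. The mean profile averages subjects;
   *reproducibility* is the median pairwise Pearson correlation of the
   subjects' log fold-change profiles (defined as 0 for flat profiles).
2. **Irreproducibility filter** (`filter_irreproducible()`). A feature is
   excluded only when reproducibility falls below the threshold (default
   0.5) *and* the mean profile departs from flat by more than `flat_tol`
   (default 0.05 on the natural-log scale) at some time point. Flat-but-noisy
   features stay, as "stable". Both knobs are exposed; with the synthetic
   generator's default noise some genuinely stable features sit right at the
   flatness boundary and are excluded — harmless, because excluded features
   pass through correction unchanged and are reported separately.
3. **Clustering** (`cluster_drift_profiles()`). Hierarchical agglomerative
   clustering, average linkage, Euclidean distance on log mean profiles.
   The number of clusters is chosen by maximum mean silhouette width over
   `k_range` (default 2–30); ties go to the smallest k (parsimony,
   determinism); identical profiles collapse to one cluster. These choices
   are deterministic and auditable; the clustering is *not* a claim that the
   original study used exactly this algorithm.
4. **Anchored spline** (`fit_drift_fn()`). A natural cubic spline through
   the cluster-mean fold-changes — interpolating with ≤ 5 time points (the
   typical design), GCV-smoothed knot values for richer designs — then
   re-anchored by dividing by its value at $t_{\mathrm{ref}}$, so
   $g_c(t_{\mathrm{ref}}) = 1$ to machine precision. Evaluation outside the
   fitted time range clamps to the boundary value (extrapolating a cubic
   outside the observed 1–36 h is unsafe). If the anchored curve dips to
   zero anywhere on a dense grid, the cluster falls back to a positive
   piecewise-linear fit with a warning: drift factors must stay positive
   for multiplicative correction.

Every input feature ends up exactly once — in a cluster or in the exclusion
list — and the model enforces this partition.

## Correction

For sample $i$ at time $t_i$ and feature $f$ in cluster $c$:

$$ x'_{if} = x_{if} \, / \, g_c(t_i). $$

Times come either from recorded metadata or from model predictions (the
legacy-sample pipeline: classify temperature, regress time with the
temperature-matched model, clamp to the fitted range, correct with the
temperature-matched drift model). Correction is multiplicative because the
profiles are fold-changes; it preserves positivity, is exactly the identity
at $t_{\mathrm{ref}}$, and commutes with per-feature rescaling.

## Handling prediction (rdCV random forests)

`rdcv_fit()` implements random-forest classification (temperature) and
regression (delay time) with recursive, *unbiased* variable selection:

* per repetition, samples are split into `n_outer` stratified outer
  segments (classification: per-class round-robin; regression: fold labels
  permuted within consecutive outcome-ordered blocks, so every fold spans
  the outcome range);
* for each outer segment, inner `n_inner`-fold CV on the remainder ranks
  variables by forest impurity importance and recursively keeps the top
  `var_ratio` (default 0.75) fraction down to 2 variables; the count
  minimizing inner fitness (misclassification count, or RMSEP) wins, with
  ties to the fewest variables;
* the held-out outer segment is predicted at that count — variable ranking
  never sees the outer segment, which is precisely what makes the selection
  unbiased;
* per-sample predictions aggregate over repetitions (mean vote fractions or
  mean predicted hours), giving the cross-validated error: $Q^2 = 1 -
  \mathrm{PRESS}/\mathrm{TSS}$ from held-out predictions only, while $R^2$
  is computed from the consensus forest refit on all data and is therefore
  optimistic by construction ($Q^2 \le R^2$).

When `subjects` are supplied, all samples of a subject stay in the same
fold (repeated-measures leakage guard), on by default throughout the
package's own pipelines. Consensus variable sets of minimal, middle
(geometric mean) and maximal size are kept; external prediction uses the
middle set.

**Permutation testing** (`rdcv_permutation()`) refits the whole procedure on
outcome-permuted data. Besides the empirical p-value
$(\#\{\text{null} \le \text{observed}\} + 1)/(n_{\mathrm{perm}} + 1)$, a
one-sided Student-t tail probability on the standardized null is reported:
a genuinely strong model beats every permutation, and only the parametric
tail can resolve significance below the empirical floor. Null refits may
use fewer repetitions than the observed model (recorded in the result) to
keep 20–100 refits tractable.

## Evaluation

`correction_report()` computes per-feature CVs before and after correction,
aggregates per cluster, and tests each cluster's improvement with a
two-sided Wilcoxon signed-rank over member features' paired CVs (a
nonparametric paired choice; a paired t-test would assume normality of CVs).
The CV is computed **within each subject's time course and averaged over
subjects** by default: this isolates handling-induced plus analytical
variation and is the only definition compatible with amino-acid cluster CVs
in the 5–6% range, since pooling across subjects would add a between-person
variance floor an order of magnitude larger. The pooled variant remains
available via `cv_mode = "pooled"`.

`deviation_surface()` pools within-subject relative deviations from the 1 h
state across subjects × features per time point and returns requested
percentiles — the "isobaric line" view of global feature stability.
`compare_predicted_groups()` applies one-way ANOVA with Tukey-HSD-adjusted
pairwise comparisons to predicted times over coarse handling labels.

## The synthetic study generator

`simulate_handling_study()` generates

$$ x(s, f, t, T) = \mathrm{base}_f \cdot \eta_{sf} \cdot g_{c(f),T}(t)
   \cdot d_{\mathrm{sample}} \cdot \varepsilon, $$

all factors log-normal: per-feature baselines, per-subject-per-feature
level effects, a per-sample dilution (removed by PQN) and measurement
noise. Defaults emulate a two-temperature handling experiment: 16 subjects
× delay times {1, 3, 8, 24, 36} h × {4, 22} °C × 478 features, with ~6% of
features drifting irreproducibly (random per-subject sign and scale, so no
common drift function exists).

Design choices that matter, and why:

* **Curves anchored at blood draw (t = 0).** Drift starts when blood meets
  the tube, not at the first sampled time point; the 1 h samples at the two
  temperatures therefore already differ slightly, as observed in real
  handling experiments.
* **Temperature-specific kinetics.** Each archetypal cluster carries its
  own saturation time constants per temperature (`tau_warm`, `tau_cold`)
  and a cold effect size (`effect_cold`, default the warm effect divided by
  `temp_factor` = 3). The default mix: a lactate-like slow rise (τ 6 h warm
  / 30 h cold), a pyruvate-like fast rise essentially frozen in the cold
  (τ 2 h / 50 h) — a temperature marker; a glucose-like decrease with its
  own sensitivity (τ 18 h / 9 h); a cold-only monotone increase emulating
  cold-induced release of intracellular metabolites (hemolysis-like); a
  cold-only transient 3 h excursion; and stable features. If the cold
  curves were merely amplitude-scaled copies of the warm curves, any cold
  sample would mimic some earlier warm sample (a time-rescaling degeneracy)
  and temperature would be essentially unpredictable — contrary to what
  handling experiments show. Temperature recognisability requires processes
  with *different* relative speeds, which is also the biology.
* **Heterogeneous between-person variance.** Per-feature subject-level sd
  is `subject_level_sd` × a log-normal(0, 0.6) multiplier: plasma
  metabolites span a wide range of inter-individual variance, and the
  usable handling markers are exactly the tightly regulated ones.
* **Shared feature population across batches.** Baselines and subject-level
  sds derive from a sub-seed of the config seed, so a legacy batch
  (`simulate_legacy_batch()`: independent donors, coarse time labels only,
  a global multiplicative batch factor) measures the *same* features as the
  training batch — the premise of external prediction.

`truth_labels()` returns, per temperature, the partition a clustering run
can actually recover: planted clusters whose curves coincide at that
temperature (e.g. the cold-only archetypes are flat at 22 °C) share a
label. The generator is bit-reproducible under its seed.

What the generator does **not** emulate: real NMR peak-shape artifacts and
alignment error, correlated features from one metabolite's multiplet
structure, non-stationary subject physiology, and drift kinetics beyond
saturating exponentials and one transient bump. Passing recovery tests on
this generator therefore demonstrates the machinery is correct and
calibrated under its assumptions, not that real plasma obeys them.

## Numerical choices and problem sizes

* Anchors hold to 1e-10; serialization stores spline knots and values in
  JSON and reproduces evaluations to machine precision (forests are refit
  deterministically from the stored training data and seed on load).
* All randomness derives from explicit integer seeds; identical seed +
  config + data give bit-identical results (ranger is run single-threaded
  with fixed seeds for both training and prediction).
* The test-suite and acceptance computations run the full default design
  (160 samples × 478 features) for drift modeling and correction, rdCV
  with 3 repetitions × 5 outer × 4 inner folds and 200 trees, 20
  permutations with single-repetition null refits, and the permutation
  calibration study on compact 24-sample problems. These sizes were chosen
  so the whole validation runs comfortably on a laptop core while leaving
  the measured quantities stable across seeds.

## Known limitations

* With 5 design time points the spline is an interpolant; sharp kinetics
  between sampled times (e.g. a sub-3 h transient) are captured only as far
  as the sampling allows.
* The irreproducibility filter is a per-feature marginal criterion; a
  cluster-aware criterion could keep weakly reproducible members of strong
  clusters.
* $R^2$ from the refit consensus forest is optimistic; rely on $Q^2$ for
  generalization claims, as the reports do.
* Per-subject drift CVs are bounded by the planted effect sizes (max |log2
  fold-change| 1.0), so the default scenario produces almost no features
  with CV > 30%; the proportion-above-threshold summaries are most
  informative on stronger-drift configurations.
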