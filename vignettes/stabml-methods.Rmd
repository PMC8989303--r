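---
title: "Methods: stabilized repeated-CV modeling for small clinical cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stabilized repeated-CV modeling for small clinical cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

In small clinical cohorts (here: tens of patients, dozens of
predictors), the random partitioning of data into cross-validation
folds is an implicit modeling parameter. Model performance, permutation
feature importance (pFI), and any pFI-driven process such as backward
feature elimination all vary with the partitioning arrangement. `stabml`
treats one partitioning arrangement as a *project* and makes repeated
projects the unit of every analysis: performance, importance, partial
dependence, reduction decisions, validation predictions and best-F1
thresholds are all aggregated across projects as a mean with a 95%
confidence interval.

## The model pipeline and its assumptions

A *blueprint* fixes a preprocessing + estimator recipe applied inside
every fold, with all statistics (imputation medians, bin edges,
standardization, one-hot levels) fitted on the training folds only:

- **Quintile-binned L2 logistic regression** (`bp_logistic()`): numeric
  columns are imputed with the training-fold median and encoded as
  indicators of the quintile bins whose edges are the training-fold
  20/40/60/80 linear-interpolation percentiles. Duplicate edges, and an
  edge equal to the training maximum, are dropped, so heavily tied or
  constant columns degrade to fewer bins rather than erroring. The
  binning is what produces piecewise-constant partial dependence: all
  values inside one training quintile are indistinguishable to the
  model. The estimator is ridge-penalized logistic regression (glmnet,
  `alpha = 0`), with `lambda = 1/(n * C)` and default `C = 1`.
- **Gradient-boosted trees** (`bp_gbt()`): numerics standardized,
  categoricals one-hot encoded (a documented stand-in for learned
  categorical embeddings, which this package does not implement), and a
  compiled exact-greedy boosted-tree classifier with logistic loss and
  second-order leaf values (`leaf = -Σg / (Σh + λ)`). Defaults: 500
  trees, learning rate 0.05, depth 3, `λ = 1`. There is no row or
  column subsampling, so fits are deterministic by construction.
- **Majority-class benchmark** (`bp_majority()`): predicts the
  training-fold prevalence; its pooled out-of-fold LogLoss is the
  outcome entropy, the floor any useful model must beat.

Out-of-fold predictions are pooled for `cv_logloss`/`cv_auc`; per-fold
values are kept as well. Probabilities are clipped at `1e-15` before
logs.

### Permutation importance

pFI is computed on the *held-out* fold of each fold model: one feature's
values are shuffled, the LogLoss increase is averaged over
`n_permutations` (default 10) shuffles, fold values are averaged within
the project, negatives are floored at 0, and the list is normalized so
the maximum is 1. The held-out choice avoids resubstitution optimism;
whether the reference platform used held-out or training data for its
importance is unknown, so this is documented as this package's
convention, not a reconstruction. Because every fitted encoder is a
per-column map, shuffling a raw column commutes with encoding; the
implementation permutes rows of the encoded block, which is equivalent
and much faster.

### Partial dependence

For a grid value `v`, the feature column is set to `v` for every record
and predictions are averaged. Numeric grids use the unique values when
there are at most 25, else 25 equally spaced quantiles of the *full*
table, so grids are identical across projects and poolable. The
project-level curve averages the project's fold models; cross-project
aggregation then reflects partition-induced variability, which is the
quantity of interest.

## Stability metrics

- **Standardized performance CI width** = CI width / mean × 100. CIs
  are Student-t on `n − 1` df over per-project values — the paper-style
  "mean and 95% CI" phrase does not pin down a method, and t is the
  small-n default; a percentile bootstrap is available as an option.
- **FRI** between two pFI lists is the L1 distance between their rank
  vectors over shared features (re-ranked within the shared set). Ties
  in mean importance break by descending importance then ascending
  feature name, for determinism. The bottom-k variant sums only the k
  least-important features of the *reference* (smaller/earlier)
  aggregate, using full-list ranks.
- Both **sampling analyses** draw projects one at a time without
  replacement, recompute the metric at each aggregate size, and repeat
  (default 1000 replicates). For FRI, each aggregate is compared to the
  previous aggregate's ranking; at size 2 the reference is the first
  drawn project's own list. Inputs are put in a canonical order before
  seeded sampling so the curves are simultaneously bit-reproducible
  under a fixed seed and invariant to the order in which project
  results are supplied.

## Backward feature reduction

Phase 1 repeats: fit the blueprint across all projects, aggregate pFI,
remove the 5 lowest-mean-pFI unprotected features — when a protected
feature falls in the elimination set, the next lowest unprotected
feature is taken instead — while more than 5 unprotected features
remain (models with zero features are never fitted). Phase 2 refits
with step size 1 across the window `best ± 5` (clipped) around the
phase-1 LogLoss optimum; the exact window rule used by the reference
workflow is not stated, and the symmetric window is this package's
documented default. Selection minimizes mean cross-validated LogLoss,
ties toward fewer features. Per-step FRI over surviving features
quantifies how much elimination reshuffles the remaining ranking.

## Hemodynamic features and the threshold sweep

Vitals series are summarized as mean, sd (n−1), Fisher–Pearson skew and
excess kurtosis (bias-uncorrected), ignoring timing; undefined moments
are missing values, not errors. Time outside a MAP threshold uses an
explicit integration convention for possibly irregular sampling: each
sample owns the interval to its successor, the last sample owns the
median sampling interval, and equality at the threshold counts as
inside range (the reference's integration rule is unstated). The sweep
fits, on identical partition plans, a no-threshold baseline plus one
single-threshold feature list per integer candidate (lower 70–85, upper
95–115 mmHg; 38 conditions), so performance differences are
attributable to the feature definition alone.

## Validation scoring and drift auditing

Each project contributes the mean of its fold models' probabilities per
validation patient; nothing is refitted on validation data. A patient is
called improved iff the across-project mean probability strictly
exceeds the across-project mean best-F1 threshold (thresholds are
midpoints between consecutive sorted unique out-of-fold probabilities,
plus 0 and 1; F1 ties break toward the lower threshold).

PSI uses 10 training-quantile bins for numerics (duplicate edges
collapsed), one bin per level for categoricals, natural log, and an
empty-bin proportion floor of `1e-4` — the reference delegates its PSI
recipe to an external citation without formulas, so these are explicit
defaults. Quantile binning makes numeric PSI invariant under strictly
monotone transforms. Classes: `< 0.1` none, `0.1–0.25` moderate
(closed at both ends, since the source text uses `>` and `<` loosely),
`> 0.25` significant.

Cohort clustering pools both cohorts on the chosen features, removes
records with any missing value (listwise deletion), scales numerics,
one-hot encodes categoricals, embeds to 2-D with UMAP (uwot,
single-threaded for reproducibility under the embedding seed), and
clusters the embedding. No HDBSCAN implementation is available in the
supported dependency set, so the density-style adapter is single-linkage
hierarchical clustering cut at the largest cluster count whose clusters
all meet the minimum size (default 8); undersized fragments force a
coarser cut rather than a noise label. The adapter is pluggable
(`method = "pca"` provides a linear embedding fallback), and PSI and the
cluster summaries never depend on the embedding choice.

## The synthetic cohort: what it does and does not emulate

`simulate_cohort()` states a world shaped like a small SCI surgical
registry: 74 patients; intraoperative HR/SysBP/DiaBP/MAP traces sampled
every minute over 150–360 min surgeries, first-order autoregressive
(ρ = 0.9) around patient baselines, with Poisson-count random-onset,
exponential-duration excursion episodes (~22 mmHg) that push MAP beyond
the 76/104 mmHg thresholds — producing realistic time-outside-threshold
distributions with mass at zero; 46 predictors (16 moment summaries, 2
threshold features, ordinal `AIS_ad` and `MRI_1_BASIC_Score`, three
binary injury covariates, log-normal `Time_to_OR` in hours, 22 noise
features); and a Bernoulli outcome from a logistic model on the true
feature values whose intercept is calibrated by bisection to the 39/74
prevalence. The drifted validation generator (59 patients, 14/59
prevalence) halves-plus the median time-to-surgery (×0.4) and
suppresses hypotensive excursions (×0.25), emulating evolving clinical
practice, with the outcome model unchanged.

Unspecified magnitudes (baselines, AR parameters, excursion rates,
coefficient sizes) were chosen once as clinically plausible values and
are not tuned. The generator does not emulate: informative missingness
(missingness is MCAR at 1% per cell), correlation between severity
scores and hemodynamics, waveform-level physiology, or measurement
artifacts. A green recovery test therefore establishes that the
pipeline recovers planted structure under partition noise — not that it
would recover structure under real-world confounding.

## Numerical and degenerate-input choices

- Probability clipping `1e-15`; LogLoss on empty input errors.
- AUC by midranks (ties count half); single-class inputs error.
- glmnet non-convergence triggers one retry at 10× the penalty, then a
  hard error; a single-column design is padded with a zero column to
  satisfy the solver.
- Constant numeric columns: one quintile bin; sd used for
  standardization is replaced by 1.
- Unseen categorical levels at prediction time map to an all-zero
  one-hot row (ordinal: code 0).
- Partition plans require every class in at least `k` groups and fail
  loudly otherwise; group class is the majority class of its members.
- Project seeds are drawn without replacement from a stream determined
  by the master seed, guaranteeing distinctness and reproducibility.

## Known limitations

- pFI overestimates correlated features' importance (shared credit);
  the collinearity behavior is demonstrated, not corrected. SHAP-style
  attributions are out of scope.
- The blueprint search of a full AutoML platform (80–90 candidate
  recipes) is out of scope; exactly the declared blueprints run.
- The clustering adapter approximates density-based hierarchical
  clustering; cluster *boundaries* have no significance beyond the
  minimum-size rule.
- Reduction retrains at every step for every project; cost grows as
  (steps × projects × folds), which is why the test suite runs reduced
  project counts (the code path is identical).
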