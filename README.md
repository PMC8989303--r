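# stabml

Reproducibility-hardened machine learning for small clinical cohorts.

Clinical prognostic studies of rare disorders — the motivating case is
acute spinal cord injury (SCI), where a registry may hold fewer than a
hundred surgical patients against dozens of candidate predictors — face
a specific failure mode: the *partitioning arrangement* of a
cross-validation run becomes a hidden hyperparameter. Two fits of the
same model on the same data with different fold assignments can disagree
about performance and, worse, about which features matter. `stabml`
packages the countermeasures:

- **Repeated-CV "projects"**: `n` independent stratified, group-aware
  10-fold partitionings of one cohort; every downstream quantity is
  aggregated across projects as a mean with a Student-t 95% CI.
- **Performance precision**: the *standardized performance CI width*,

  ```
  width% = (CI_high − CI_low) / mean_performance × 100
  ```

  with a sampling analysis of how it shrinks as projects are aggregated.
- **Feature rank instability (FRI)** between two permutation-feature-
  importance (pFI) lists `p`, `q` over shared features `i = 1..f`:

  ```
  FRI = Σ_i | rank_p(i) − rank_q(i) |
  ```

  plus a bottom-k variant and the aggregation-vs-stability sampling
  analysis.
- **Stabilized explanation**: held-out permutation feature importance
  (normalized to the maximum) and partial dependence, aggregated across
  projects with CIs.
- **Expert-protected backward feature reduction**: remove the five
  lowest mean-pFI features per step (protected features are skipped in
  favor of the next lowest), then refine with step size 1 inside the
  window around the LogLoss optimum, and select the parsimonious list.
- **Hemodynamic feature engineering**: per-signal moment summaries
  (mean/sd/skew/kurtosis of HR, SysBP, DiaBP, MAP) and
  time-outside-MAP-threshold features (`time_MAP_Avg_above_104`,
  `time_MAP_Avg_below_76`), with a single-threshold sweep over lower
  70–85 and upper 95–115 mmHg (1 + 16 + 21 = 38 conditions).
- **External validation and drift auditing**: per-patient mean
  predictions vs the mean best-F1 threshold; per-feature population
  stability index (PSI; <0.1 none, 0.1–0.25 moderate, >0.25
  significant); pooled-cohort UMAP embedding and minimum-cluster-size
  clustering with per-cluster summaries.
- **A seeded synthetic SCI-like cohort generator** (74 patients, 46
  predictors, 39/74 outcome prevalence, autoregressive intraoperative
  vitals with threshold-crossing excursion episodes, plus a drifted
  59-patient validation-era cohort) so the whole workflow is testable
  without clinical data.

Blueprints (preprocessing + estimator recipes) included: quintile-binned
L2 logistic regression (`bp_logistic()`), gradient-boosted trees with
one-hot categorical encoding (`bp_gbt()`, compiled via Rcpp), and the
majority-class benchmark (`bp_majority()`).

## Worked example

```r
library(stabml)

sim <- simulate_cohort(cohort_config(), seed = 42)
sim$table
#> <feature_table> 74 patients x 46 predictors (45 numeric, 1 categorical)
#>   target: 37 improved / 37 not (prevalence 0.500)

projects <- make_project_set(sim$table, k = 10, n_projects = 25,
                             master_seed = 7)
results <- fit_projects(bp_logistic(), sim$table, projects,
                        n_permutations = 5)
aggregate_values(vapply(results, `[[`, numeric(1), "cv_logloss"))
#> <aggregate> n=25 mean=0.7020 95% CI [0.6837, 0.7203]

head(aggregate_pfi(results), 3)
#>     feature importance    ci_low   ci_high n_projects rank
#> 31 noise_09  0.9587679 0.9221928 0.9953430         25    1
#> 35 noise_13  0.7716653 0.7012270 0.8421037         25    2
#> 6     HR_sd  0.4272334 0.3211315 0.5333353         25    3

curve <- precision_sampling_analysis(results, n_draws = 1000, seed = 1)
curve[curve$size %in% c(2, 25), ]
#>    size      mean    ci_low   ci_high
#> 1     2 90.239125 85.854237 94.624013
#> 24   25  5.204829  5.204829  5.204829
```

Three things worth reading off this output. The blueprint's mean
cross-validated LogLoss is 0.70 with a CI width of 5.2% of the mean once
25 projects are aggregated — at 2 projects the expected width is 90% of
the mean, i.e. single-repetition performance numbers at this sample
size are close to meaningless. Second, the top-ranked "important"
features in this 74-patient draw are two pure-noise columns: with 46
predictors and 74 patients a spurious correlate can dominate even a
properly aggregated importance ranking. That is not a bug in the
metric; it is the small-cohort failure mode the package exists to make
visible, and it is why the workflow continues with feature reduction,
external validation and drift auditing rather than stopping at an
importance plot. (At n = 300 with the planted-signal generator,
`aggregate_pfi` ranks all true signal features above all noise features
in ≥ 95% of seeded replicates — see the acceptance suite.)

Downstream stages follow the same pattern:

```r
trace <- backward_reduce(bp_logistic(), sim$table, projects,
                         protected = "time_MAP_Avg_below_76")
pars  <- select_parsimonious(trace)
sw    <- threshold_sweep(bp_logistic(),
                         setdiff(pars$features,
                                 grep("^time_MAP", pars$features, value = TRUE)),
                         sim$table, sim$vitals, projects)
vsim  <- simulate_drifted_cohort(cohort_config(), drift_spec(), seed = 43)
score <- score_validation(fit_projects(bp_logistic(), sim$table, projects,
                                       features = pars$features,
                                       compute_pfi = FALSE),
                          vsim$table)
drift <- drift_report(sim$table, vsim$table, pars$features)
```

A command-line wrapper mirroring these stages
(`simulate | run | stability | reduce | sweep | validate | drift`) is
provided in `inst/cli/stabml.R`:

```sh
Rscript inst/cli/stabml.R simulate --out scratch/demo --seed 1
Rscript inst/cli/stabml.R run --out scratch/demo --seed 1 --blueprint BP_log
```

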