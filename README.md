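# jmscreen

Joint modeling of longitudinal biomarkers and time-to-event outcomes for
dynamic disease-risk prediction and proteome-wide screening.

## What it is for

Longitudinal omics studies — the motivating case is plasma proteomics in
children followed from infancy towards possible type 1 diabetes onset —
measure each subject's biomarkers repeatedly and record a time-to-event
outcome.  Two questions drive the analysis:

1. **Dynamic prediction.** Given a subject's biomarker history up to time
   *s*, what is their probability of the event by horizon *t*?
2. **Screening.** Among thousands of features, which carry genuine
   information about that risk?

`jmscreen` answers both with four modeling routes plus the scaffolding to
benchmark and screen them:

* **Shared-random-effects joint model** — linear mixed model
  `y(t) = (β₀+b₀) + (β₁+b₁)t + ε` coupled to a Weibull
  proportional-hazards model through the current value:
  `h(t|b) = κλt^(κ−1) exp{α·m(t)}`, estimated by maximum likelihood with
  adaptive Gauss–Hermite quadrature; Wald test on the association `α`.
* **Joint latent-class mixed model** — latent subgroups with
  class-specific trajectories and class-specific Weibull hazards
  (proportional across classes), fitted by EM with multi-start grid search
  and BIC class-number selection.
* **Partly conditional Cox regression** — Cox partial likelihood on
  landmark-stacked residual times with subject-clustered robust variance.
* **Last-value Cox baseline** — the conventional single-time-point
  comparator.

Around the models: a simulator for a 45-scenario benchmark grid (3
variance levels × 5 effect sizes × 3 cohort sizes) and for proteomics-like
cohorts with planted signal features; conditional-risk prediction
`π(t|s) = 1 − E[S(t|b)/S(s|b) | history, T > s]`; AUROC with DeLong 95%
CIs; paired Wilcoxon method comparison; and a screening pipeline with
peptide/missingness prefilters, Benjamini–Hochberg adjustment, AUROC
prioritisation at successive evaluation ages, cross-method consensus, and
leave-one-out cross-validation.

See `vignettes/jmscreen-methods.Rmd` for the full model account, the
numerical choices, and the stated synthetic-data world.

## Worked example

Simulate one benchmark scenario (50 subjects per group, case slope
+0.075/year, control −0.075, residual SD 0.5, events ~N(18,1) after the
15-year follow-up), fit the joint model, and evaluate on the paired
independent test set:

```r
library(jmscreen)
cfg  <- scenario_config(n_per_group = 50, slope_coef = 0.075,
                        resid_sd = 0.5, seed = 42)
pair <- simulate_scenario_pair(cfg)
pair$train
#> longitudinal_dataset: 100 subjects, 1 features, 1000 measurements
#>   groups: case=50, control=50
#>   events: 50 observed, 50 censored

fit <- fit_joint_model(pair$train)
fit
#> Shared-random-effects joint model (Weibull baseline, current-value association)
#>   100 subjects, 50 events;  logLik -936.51987;  converged: TRUE
#>   longitudinal: intercept 6.051, slope -0.005492, sigma 0.4919
#>   baseline: kappa 23.88, lambda 2.033e-37
#>   association alpha 2.054 (se 0.353)
wald_test(fit)$p
#> [1] 5.717931e-09

res <- evaluate_scenario(pair$train, pair$test, methods = c("jm", "cox"))
res[, c("method", "followup", "auroc", "ci_low", "ci_high")]
#>   method followup auroc ci_low ci_high
#> 1     jm        5 0.893  0.825   0.961
#> 2     jm       10 1.000  1.000   1.000
#> 3     jm       15 1.000  1.000   1.000
#> 4    cox        5 0.852  0.776   0.928
#> 5    cox       10 0.978  0.958   0.999
#> 6    cox       15 0.998  0.994   1.000
```

Reading the output: the population slope is ~0 (the two groups cancel),
but the association `α = 2.05` (Wald p ≈ 6e-9) says subjects whose own
trajectories run higher face proportionally higher hazard — exactly the
planted structure.  The joint model's AUROC for predicting 20-year status
drops from 1.00 with the full 15-year history to 0.89 with only 5 years,
and the last-value Cox baseline trails it at every follow-up length.

Screening a simulated cohort (21 subjects, planted features) looks like:

```r
coh  <- simulate_cohort(n_features = 200, n_assoc = 5, seed = 1)
rows <- screen_cohort(coh, methods = c("jm", "pccox"))
cons <- consensus(rows)            # features selected by >= 2 methods
cv   <- loocv_screen(coh, cons$feature_id, "pccox")
```

A command-line interface covers the same ground:
`Rscript -e 'jmscreen::jmscreen_cli()' simulate --seed 1 --out sims/`
(subcommands `simulate`, `benchmark`, `screen`, `loocv`).

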