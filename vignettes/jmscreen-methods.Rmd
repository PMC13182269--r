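---
title: "Joint modeling of longitudinal biomarkers and time-to-event outcomes: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{jmscreen methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jmscreen)
```

## The problem

In longitudinal biomarker studies — the motivating setting is plasma
proteomics in children followed from infancy towards possible type 1
diabetes onset — each subject contributes a short series of abundance
measurements and a time-to-event outcome (disease onset, or administrative
censoring for controls).  The scientific question is dynamic: given a
subject's biomarker history up to time $s$, what is their probability of
the event by a horizon $t$?  And, proteome-wide: which of thousands of
features carry information about that risk?

`jmscreen` implements four modeling routes to that question, a simulation
engine that generates benchmark data under controlled signal/noise
conditions, AUROC-based evaluation, and a per-feature screening pipeline
with multiplicity control, cross-method consensus, and leave-one-out
cross-validation.

## Models

### Longitudinal submodel

For one feature, the trajectory model is the random-intercept/random-slope
linear mixed model

$$y_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\,t_{ij} + \varepsilon_{ij},
\qquad b_i \sim N(0, D), \quad \varepsilon_{ij} \sim N(0, \sigma^2).$$

Estimation is by maximum likelihood (not REML): the joint model's
likelihood is an ML object, and using ML throughout makes the
zero-association factorisation below an exact identity rather than an
approximation.  The per-subject marginal Gaussian likelihood is evaluated
from sufficient statistics with the Woodbury identity, and $D$ is
parameterised by its log-Cholesky factor, so the optimisation is
unconstrained and $D$ is positive definite by construction.

### Shared-random-effects joint model

The survival submodel couples the subject's *current model-implied value*
$m_i(t) = (\beta_0+b_{0i}) + (\beta_1+b_{1i})t$ to a Weibull
proportional-hazards baseline:

$$h_i(t \mid b_i) = \kappa \lambda t^{\kappa-1} \exp\{\alpha\, m_i(t)\}.$$

There are no exogenous survival covariates (the baseline survival formula
is intercept-only, matching the screening setting where the feature itself
is the only predictor).  The marginal likelihood integrates $b_i$ out.  We
use the exact factorisation

$$p(y_i, T_i, \delta_i) = p(y_i)\; E_{b \mid y_i}\!\left[
h_i(T_i\mid b)^{\delta_i} e^{-\Lambda_i(T_i \mid b)}\right],$$

where $p(y_i)$ and the posterior $b \mid y_i$ are closed-form Gaussians.
The expectation is evaluated by Gauss-Hermite quadrature (default 9 nodes
per dimension, 81 bivariate nodes) *centred on that posterior* — the
adaptive placement means the rule only has to integrate the smooth survival
factor.  Two consequences worth noting:

* at $\alpha = 0$ the survival factor does not depend on $b$, so the
  likelihood separates **exactly** into the LMM likelihood plus a censored
  Weibull likelihood, at any number of quadrature nodes;
* the cumulative hazard $\Lambda_i(T \mid b)$ is computed by Gauss-Legendre
  quadrature after the substitution $v = (u/T)^\kappa$, which absorbs the
  Weibull kernel: the rule integrates $\exp\{\alpha m_i(T v^{1/\kappa})\}$
  on $[0,1]$, is exact at $\alpha = 0$, and never evaluates the
  $u^{\kappa-1}$ singularity.

Estimation is quasi-Newton (BFGS) on the 9-dimensional working vector
(fixed effects, log-Cholesky of $D$, $\log\sigma^2$, $\log\kappa$,
$\log\lambda$, $\alpha$), initialised from the standalone LMM fit plus a
null censored-Weibull fit with $\alpha = 0$.  Standard errors come from the
central-difference numerical Hessian of the negative log-likelihood at the
optimum, with an eigenvalue-thresholded pseudo-inverse fallback (and a
warning) when the observed information is ill-conditioned.  Significance of
the association is the Wald test $z = \hat\alpha / \mathrm{se}(\hat\alpha)$.

Non-convergence is treated as data, not as an exception: the fit is
returned with `converged = FALSE`, and evaluation/screening code reports
the row with a reason code.  This mirrors the empirical behaviour of
maximum-likelihood joint models, which fail to converge on an appreciable
fraction of hard scenarios; in very small cohorts with very strong
associations the likelihood develops a separation-like ridge along which
$\alpha$ and $\kappa$ grow together, and an honest flag is more useful
than a forced number.

### Joint latent-class mixed model

The latent-class variant replaces the shared-random-effect coupling with a
finite mixture: each subject belongs to one of $G$ latent classes with
class-specific fixed intercept/slope and class-specific Weibull hazards
under a proportional-hazards constraint (shared shape $\kappa$,
class-specific rates $\lambda_g$); $D$ and $\sigma^2$ are shared across
classes, and conditional on class the longitudinal and survival processes
are independent.  The per-subject likelihood is then available in closed
form, and estimation is plain EM:

* E-step: posterior class probabilities from the product of the
  longitudinal marginal density and the class Weibull survival density;
* M-step: closed-form mixing proportions, BFGS update of the weighted
  longitudinal parameters, and a profile update of the Weibull part
  (rates closed-form given the shape, shape by 1-D optimisation).

Design choices where the published strategy is silent: random effects are
shared across classes (class-specific fixed effects only), keeping the
parameter count workable at 21-subject scale; class membership is
intercept-only multinomial (no covariates are mentioned anywhere in the
strategy); "proportional hazards across classes" is implemented as the
minimal structure satisfying it — shared Weibull shape with class-specific
log-rate offsets.  The number of classes (1 or 2) is chosen by BIC
($-2\ell + k\log n_{\text{subjects}}$), with a multi-start grid search
(default 10 Gaussian-jittered perturbations of the one-class start,
magnitude-scaled) guarding against local optima; ties in BIC go to the
smaller class number.  With one class the fit reduces *exactly* to the
separable LMM-plus-Weibull maximum likelihood fit.

### Cox baselines

Two non-joint comparators are included.  The **partly conditional Cox
model** stacks one row per (at-risk subject, landmark time $s$): the
covariate is the subject's marker summary at $s$ (last observed value by
default; a mixed-model smoothed current value is available), the response
is residual time $T_i - s$.  The partial likelihood is maximised with
Efron tie handling (configurable to Breslow) and subject-clustered
sandwich variance, since subjects repeat across landmarks.  The
**conventional Cox baseline** uses each subject's last observed abundance
as the sole covariate.  Both delegate the partial-likelihood machinery to
the `survival` package; monotone-likelihood (separation) is detected from
the fitter's diagnostics and the coefficient is capped at $|\beta| = 15$
with a warning.  Risk-scale predictions use the Breslow baseline hazard.

## Dynamic prediction and evaluation

The joint-model risk of a subject, given history to $s$ and event-free
survival to $s$, is

$$\pi_i(t \mid s) = 1 - \frac{\int S(t \mid b)\, p(b \mid y_i(\le s))\,db}
{\int S(s \mid b)\, p(b \mid y_i(\le s))\,db},$$

evaluated with the same posterior-centred Gauss-Hermite rule; the
denominator *is* the survival-to-$s$ conditioning, so no shortcut BLUP
plug-in is involved.  The latent-class analogue weights class-specific
Weibull conditional risks by the class posterior given history and
survival.  In observational cohorts a subject may already be past their
event at a late evaluation age; such subjects are scored from their
pre-event history (conditioning at $\min(s, T_i)$) so the status-at-horizon
AUROC remains computable for the full cohort.

Discrimination is summarised by the AUROC (Mann-Whitney estimator, ties
counted half) with a DeLong-variance normal 95% CI.  Scores are event
risks and are never orientation-flipped: a method that performs below
chance reports below 0.5.  Paired cross-method comparisons use the
two-sided Wilcoxon signed-rank test: exact for $n \le 25$ untied
differences, full $2^n$ sign-assignment enumeration for tied differences
up to $n = 16$, normal approximation with continuity correction beyond;
zero differences are dropped.

## The synthetic world

The benchmark generator reproduces a fixed scenario grid: residual SD
$\in \{0.5, 1, 1.5\}$, absolute slope $\in \{0, 0.025, 0.05, 0.075, 0.1\}$
abundance units/year (cases $+$, controls $-$), group size
$\in \{10, 50, 1000\}$ — 45 scenarios, enumerated variance-outer /
slope-middle / size-inner.  Each subject has 10 visits evenly spaced on
$[0, 15]$ years (both endpoints included; a 3-visit short-series variant
keeps the same grid), log-scale abundance centred at 6 with
random-intercept SD 0.1.  Case event times are $N(18, 1)$ truncated by
*rejection* to $(15, 20]$ — truncation keeps events after follow-up
without creating boundary atoms; controls are administratively censored at
20 years.  These choices are stated study conditions, not tuning knobs.
Where the stated world is silent we fixed, once: controls carry no latent
event time (censoring is administrative, which is what makes the
case/control AUROC at the study end well defined); each scenario's test
set is an independent draw at `seed + 100003`, same size as training; and
every subject consumes a deterministic substream of the master seed, so
subject-level draws are invariant to cohort subsetting.

The cohort generator emulates the screening setting: 11 cases / 10 matched
controls, 9 visits spanning 0.8–14.4 years of age, ~2000 features, case
onsets centred near 11.7 years.  Planted features are noisy affine
readouts of a single shared latent trajectory $m(t) = b_0 + b_1 t$
($b_0$ SD 0.3, $b_1$ SD 0.06/year) whose Weibull current-value hazard
($\kappa = 8$; baseline rate set so the baseline median onset equals the
target onset age; association $\alpha$, default 1.5) generates the onset
ages by cumulative-hazard inversion; subjects are resampled until the
case/control quotas are met.  Sharing one latent process across planted
features is deliberate: a cohort has a single event time per subject, so
independent per-feature joint laws would be mutually inconsistent — the
planted set behaves like one co-regulated disease module.  Null features
are subject-shifted noise.  Feature metadata (unique peptides 1–30,
missing values 0–15) is randomised so the prefilter genuinely filters;
planted features always satisfy the default prefilter, emulating
well-quantified proteins, and the declared missing cells are actually
deleted from the measurement table.

What the generator does **not** emulate: batch effects, isobaric-label
ratio compression, intensity-dependent missingness, or correlated null
features.  A green screening test therefore establishes that the pipeline
recovers planted current-value signal under clean Gaussian noise and
controls the FDR under an independent global null — not that it is robust
to mass-spectrometry artefacts.

## Screening

Per feature: prefilter (unique peptides $\ge 6$, missing values $\le 10$,
boundaries inclusive), model fit on the full history (resubstitution — the
honesty check is leave-one-out cross-validation, in which models are
refitted without each subject and that subject's risk is predicted
out-of-fold), evidence of association (joint-model Wald $p < 0.05$;
partly conditional Cox robust Wald $p < 0.01$; latent-class: two classes
selected by BIC with both modal classes larger than 5 subjects), AUROC at
evaluation ages 5–8 for predicting status at age 13 from measurements up
to each age, with the threshold 0.75 required at the last two ages, and at
least 5 subjects measured per class.  Benjamini-Hochberg adjusted
p-values are always emitted alongside nominal ones; selection uses the
nominal threshold by default (`use_adjusted` switches), because the
reported candidate counts in this strategy follow the nominal rule while
BH is reported for FDR context.  The consensus set contains features
selected by at least two methods.

## Numerical choices, in one place

* Quadrature: 9-point Gauss-Hermite per random-effect dimension,
  15-point Gauss-Legendre for cumulative hazards (both configurable;
  5 nodes is the accepted floor and is what the type-I-error simulation
  uses).  Increasing 9 to 15 nodes moves the log-likelihood by under
  1e-4 on benchmark-scale data.
* Optimiser tolerances: relative log-likelihood change 1e-10, max 500
  iterations; the joint fit's `converged` flag additionally requires the
  numerical gradient's infinity norm below 1e-3 (scaled).
* EM: relative tolerance 1e-8, max 200 iterations; a mixing weight below
  1e-4 is treated as class collapse and triggers restart/flagging.
* Ties: AUROC counts ties as one half; Cox ties use Efron unless Breslow
  is requested.
* Degenerate inputs: all-identical measurement times refuse a slope;
  constant markers refuse a Cox fit; datasets without events refuse joint
  estimation; subjects emptied by follow-up truncation are flagged and
  excluded from prediction with a warning.

## Known limitations

* The Wald test for the joint association is untrustworthy in very small
  cohorts with very strong signal (likelihood ridge; see above).  The
  cross-method consensus exists precisely to absorb this.
* The latent-class model shares $D$ and $\sigma^2$ across classes; strongly
  class-heteroscedastic data would be mis-modelled.
* Risk predictions for the Cox baselines use step-function Breslow
  baselines, which are coarse beyond the last observed event time.
* The LOO-CV refits use the same automated selection as the full fit but
  inherit its convergence fragility at n = 20 folds of 20 subjects.
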