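---
title: "Modelling time reallocation: ISM and CISM in isosub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling time reallocation: ISM and CISM in isosub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isosub)
```

## The two models

Daily waking behaviour is recorded by a thigh-worn accelerometer as
minutes of sitting, standing and stepping. These three durations sum to
waking wear time, so they are not free variables: any association
analysis must respect that moving time into one behaviour removes it
from another. `isosub` implements the two regression conventions in use
for this problem and makes their structural differences measurable.

**ISM.** The outcome (standardised within the analysis sample) is
regressed on standing hours, stepping hours, and total waking wear
hours, plus covariates. Sitting is the omitted behaviour, so the
standing and stepping coefficients estimate the effect of exchanging an
hour of sitting for an hour of that behaviour at fixed waking time. A
reallocation of $t$ minutes is the coefficient scaled by $t/60$;
direction reversal is a sign flip. Both identities are algebraic, not
empirical: the package's diagnostics verify them to $10^{-12}$.

**CISM.** The behaviour vector $\mathbf{x} = (\text{sit}, \text{stand},
\text{step})$ is a composition: only relative information is meaningful
once the total is fixed. It is mapped to isometric log-ratio (ILR)
coordinates $\mathbf{z} = \mathbf{V} \log \mathbf{x}$, where the
$(D-1) \times D$ contrast matrix $\mathbf{V}$ comes from a sequential
binary partition (SBP): a contrast splitting an $r$-part group from an
$s$-part group carries $+\sqrt{s/(r(r+s))}$ and $-\sqrt{r/(s(r+s))}$,
making the rows orthonormal and zero-sum. The outcome is regressed on
$\mathbf{z}$ plus covariates. A reallocation effect is
$\boldsymbol\gamma \cdot \Delta\mathbf{z}$ with
$\Delta\mathbf{z} = \mathrm{ilr}(\mathbf{x}_{\text{perturbed}}) -
\mathrm{ilr}(\mathbf{x}_{\text{base}})$, and its standard error is the
delta-method form
$\sqrt{\Delta\mathbf{z}^\top \Sigma_\gamma \Delta\mathbf{z}}$. Because
$\Delta\mathbf{z}$ is non-linear in the minutes moved and depends on
which part donates the time, CISM estimates are non-linear and
asymmetric — increasingly so as the donor part gets small relative to
the reallocation.

Assumptions shared by both: linear effects on the standardised outcome
scale, homoscedastic errors (ordinary least squares), covariates
measured without error, and cross-sectional data — estimates are
associations, not causal effects.

## Choices where the convention is genuinely open

- **SBP basis.** Any orthonormal SBP gives the same fitted values,
  reallocation estimates and SEs (coordinates differ by a rotation that
  the coefficient vector and its covariance absorb). The default is the
  pivot SBP in part order (sit, stand, step) — first balance sit vs
  {stand, step} — chosen purely so reported coordinates are
  reproducible. Basis invariance is enforced by tests to $10^{-9}$.
- **Closure constant.** Reallocations are modelled within waking wear
  time, so compositions are closed to the sum of the three parts rather
  than to 1440 min; the ILR is closure-invariant anyway.
- **Base composition.** `cism_reallocation()` defaults to the
  geometric (compositional) mean of the analysis sample, the
  convention consistent with Aitchison geometry; the arithmetic mean is
  available (`mean_method = "arithmetic"`) because descriptive tables
  print arithmetic means and reconstruction from published numbers
  needs them.
- **Zero parts.** Log-ratios are undefined at zero. The package
  refuses zeros by default and offers multiplicative replacement
  (`zero_policy = "replace"`, δ = 1 min) which preserves totals: an
  explicit policy rather than a silent recode.
- **Confidence intervals.** Both methods use the normal 1.96 critical
  value — for CISM the delta-method linear-combination formula; for ISM
  the scaled coefficient SE. With analysis samples in the hundreds to
  thousands the t-vs-normal difference is far below reporting
  precision, and a shared critical value keeps the two methods'
  intervals directly comparable.
- **Standardisation population.** Outcomes are standardised per
  analysis (complete cases for that outcome and the covariates), after
  QC exclusions. The CCRS components are standardised over the rows
  supplied to `compute_ccrs()`.
- **Ethnicity coding.** Reference-coded indicators with White European
  as reference; the deprivation score enters linearly, as it is a
  continuous index.
- **The 95% single-behaviour rule.** The denominator is waking wear
  time by default (`denominator = "wear"`); the covered-time
  alternative (`sit + stand + step`) is a switch, since summaries can
  undershoot wear through rounding.
- **Threshold openness.** "At least 10 h" is `wear_min >= 600`
  (closed bound), and 500 activPAL step events correspond to 1000
  steps (an event is one full stride of two steps).

## Tunable parameters

| Parameter | Default | Units | Where |
|---|---|---|---|
| `min_wear_min` | 600 | min | `is_valid_day()` |
| `min_step_events` | 500 | events | `is_valid_day()` |
| `max_single_behaviour` | 0.95 | fraction | `is_valid_day()` |
| `min_valid_days` | 4 | days | `participant_average()` |
| `minutes` | 60 | min | reallocation size |
| `increments` | 5–60 by 5 | min | `run_incremental_grid()` |
| `alpha` | 0.05 | — | significance flag |
| `delta` | 1 | min | zero replacement |

## The synthetic cohort generator

No participant-level dataset is distributed with the package, so a
generator (`default_params()`, `generate_cohort()`) reproduces the
statistical structure the analyses assume, calibrated to the published
pooled-cohort descriptives: behaviour means/SDs of 548 (112), 286 (96)
and 107 (40) min/day; n = 1524; age 59.8 (11.9) years; 51.7% male;
72.9% White European; medication prevalences 40.2%/27.9%; BMI 30.3
(5.7), waist 100 (14), HbA1c 5.8 (0.4). Outcome targets without a
published descriptive (lipids, blood pressure) use values typical of a
UK adult cohort at high risk of type 2 diabetes, chosen once: total
cholesterol 5.3 (1.0), HDL 1.3 (0.35), LDL 3.1 (0.9), triglycerides
1.7 (0.8) mmol/L, blood pressure 132 (16)/80 (10) mmHg; deprivation
score mean 20, SD 12.

**Composition model.** Behaviour minutes are independent log-normals,
moment-matched in closed form to the target minute-scale means and SDs
($\sigma^2 = \log(1 + s^2/m^2)$, $\mu = \log m - \sigma^2/2$). Since
the log-parts are jointly normal, the ILR coordinates are multivariate
normal — a logistic-normal composition, the geometry CISM assumes —
parts are strictly positive by construction, and waking wear time is
the sum of the parts. The minute-scale ILR covariance is
underdetermined by published means and SDs alone; independence of the
log-parts is the convention adopted here, giving exact moment matching
with no numerical calibration. A `confounding_rho` knob correlates age
with log-sitting (preserving all marginal moments) to exercise
covariate adjustment.

**Outcome model.** Each outcome is built on the standardised scale as
(composition effect) + (covariate effect) + noise. In `gamma` mode the
composition effect is $\boldsymbol\gamma \cdot (\mathbf{z} -
\mathbb{E}\mathbf{z})$ with a configurable truth vector; in `beta` mode
it is ISM-style per-hour effects of standing and stepping. The residual
SD is completed analytically so the standardised outcome has unit
variance, and the result is mapped to the raw scale by the target
mean/SD. This construction makes the fitted ISM/CISM coefficients
unbiased for the configured truths — the property the recovery and
coverage checks exploit. The default BMI truth is the $\gamma$ implied
by the published 60-min zBMI reallocation estimates (solved at run
time, not hardcoded); outcomes reported as null default to zero
composition effect.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: day-to-day autocorrelation and weekday
structure, study-specific recruitment differences beyond a label
column, measurement error in the accelerometer classification,
outcome-outcome residual correlation (outcomes share the composition
and covariate signal but have independent residuals), skewness in
outcomes such as triglycerides, and any true non-linearity or effect
modification. Recovery of the generating coefficients on this synthetic
structure validates the estimation machinery, not the substantive model
for any particular cohort.

**Day-level generator.** `generate_days()` jitters each participant's
profile multiplicatively (CV 0.15/day, cadence 70 steps per stepping
minute) and, on invalid days, breaks exactly one named wear-day
criterion after first repairing the day to validity — construction is
therefore ground truth for the QC filter, and the tests require 100%
agreement.

## Numerical notes

- ILR/inverse-ILR round-trips are exact to $10^{-9}$ over 1000 random
  compositions (tested); `inverse_ilr()` subtracts the row maximum
  before exponentiating as an overflow guard.
- Reallocation requires the donor part to stay strictly positive
  (`minutes < comp[from]`, strict), so perturbed log-ratios are always
  defined; infeasible cells in the incremental grid are flagged and
  skipped, not fatal.
- A rank-deficient design (e.g. duplicated covariates) is an error
  naming the collinear columns, not a silent `NA` coefficient.
- Degenerate inputs error early with named reasons: all-zero
  compositions, constant outcomes (which cannot be standardised),
  malformed SBPs.
- One regression is fitted per (method, outcome); all increments derive
  from that fit, since coefficients do not depend on the increment. A
  `refit_per_increment` flag performs the literal per-increment refits
  for fidelity with analyses quoting one model per increment; the tests
  confirm the results are identical.
- No multiple-testing adjustment is applied; the significance flag is
  per-test at the chosen `alpha`.

## Problem sizes used in the checks

The shipped test suite works at the published cohort size (n = 1524)
for calibration, identity and worked-example checks; moment matching is
verified at n = 100{,}000; interval coverage and bias use 200 replicate
cohorts of n = 1524; the round-trip property suites use 1000 random
compositions. These sizes make the full suite run in well under a
minute on a laptop while keeping Monte-Carlo error inside the stated
bands (the 99% binomial band around 0.95 at 200 replicates is about
±0.04).

## Limitations

Estimates are cross-sectional associations under linear, homoscedastic
models; the CISM CI is delta-method (first-order) rather than
bootstrap, although a bootstrap could be layered on the exported fit
objects; three behaviours are the tested configuration even though the
log-ratio machinery is generic in the number of parts; and the
incremental comparison inherits whatever base composition is chosen —
cohorts with different mean compositions will show different degrees of
CISM asymmetry.
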