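---
title: "A survival regression-discontinuity design for the 1984 Danish parental-leave extension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A survival regression-discontinuity design for the 1984 Danish parental-leave extension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design

In July 1984 Denmark extended paid parental leave from 14 to 20 weeks.
Because women who had started their 14-week leave before 1 July 1984 were
also covered, eligibility was a deterministic step function of the child's
birth date: the first eligible birth date is

$$\text{cut-off} = \text{reform date} - 7 \times 14 \text{ days} + 1
  = \text{26 March 1984}.$$

Comparing mothers who gave birth just before and just after this cut-off is
a sharp regression-discontinuity (RD) design: the running variable is
$u = (\text{birth date} - \text{cut-off})/365.25$ years, treatment is
$\mathbb{1}\{u \ge 0\}$, and — since nobody chooses a birth date with
week-level precision against an administrative threshold — eligibility is as
good as random near the cut-off.  `leaverdd` implements this design for a
time-to-event outcome, the first inpatient psychiatric diagnosis of the
mother after the birth, with follow-up of up to 30 years.

The package has five analysis layers, each exposed as plain functions over
data frames:

1. **Cohort construction** (`build_cohort`): running variable, treatment
   flag, follow-up time to event or censoring (death, emigration,
   administrative cut-off 2017-12-31, and a 30-year cap on follow-up —
   the registry analysis reports mean 27.7 / median 30.0 / max 30 years),
   mother cluster ids, exclusion logging.
2. **First stage** (`estimate_leave_jump`, `takeup_summary`,
   `daily_mean_series`, `density_test`): the discontinuity in leave days at
   the cut-off, take-up of the extension, and a manipulation check on the
   birth-date density.
3. **Outcome model** (`fit_hazard_model`,
   `predict_cumulative_incidence`, `estimate_risk_differences`,
   `km_curves`): the survival-RD estimator described below.
4. **Heterogeneity and robustness** (`subgroup_rdd`, `interaction_test`,
   `placebo_reforms`, `bandwidth_sweep`, `era_adjusted_fit`,
   `restrict_firstborn`).
5. **Synthetic registry generator** (`generator_params`,
   `generate_registry`, `calibrate_hazard_ratio`): the Danish registry data
   are access-restricted, so the package ships a generator that emulates
   their statistical structure with every planted parameter recoverable by
   the pipeline above.

## The outcome model

The core estimator is a proportional-hazards partial-likelihood fit with
the reform groups as strata and years since birth as the time scale,

$$\lambda_g(t \mid u) = \lambda_{g0}(t)\,
  \exp(\beta_1 u + \beta_2 u^2), \qquad g \in \{\text{control},
  \text{eligible}\},$$

so the treatment contrast lives entirely in the two baseline hazards while
the shared quadratic trend in $u$ absorbs smooth cohort drift (secular
trends in diagnosis rates across birth years).  Standard errors are
cluster-robust sandwich estimates aggregating score residuals by mother,
because a mother can contribute births on both sides of the cut-off.  Ties
are handled by Breslow's method, matching the Breslow estimator used for
the per-stratum baseline cumulative hazards $\Lambda_{g0}$.

Cumulative incidence is predicted **at the cut-off**,

$$F_g(t) = 1 - \exp\{-\Lambda_{g0}(t)\, e^{\beta_1 \cdot 0 + \beta_2
  \cdot 0}\} = 1 - \exp\{-\Lambda_{g0}(t)\},$$

which removes the cohort trend and makes the two strata directly
comparable; this is the "adjusted for the cohort effect" reading of the
design.  Prediction at the sample covariate distribution is available via
the `at_u` argument of `predict_cumulative_incidence` for sensitivity.
The estimand is the horizon-specific risk difference

$$RD_h = 1000\,[F_{\text{control}}(h) - F_{\text{eligible}}(h)],$$

positive when the eligible group has *fewer* diagnoses.  Because this
literature prints the same quantity with either sign convention, the table
carries both `rd_per_1000` (control minus treated) and
`rd_treated_minus_control`.

### Simulation-based intervals

Uncertainty for $RD_h$ comes from joint parametric simulation
(`n_sims` draws; 100 000 at reference scale, 2 000–10 000 at desk scale):

* coefficient draws $\beta^* \sim N(\hat\beta, \hat V_{\text{cluster}})$;
* baseline increments respond to the coefficient draw through their
  risk-set denominators, $d\Lambda_k(\beta^*) \approx d\Lambda_k
  \exp\{-\bar x_k'(\beta^* - \hat\beta)\}$ with $\bar x_k$ the risk-set
  weighted covariate mean at event time $k$ — omitting this term leaves
  the extrapolation-to-cut-off variance out of the interval and produced
  ~74% coverage instead of ~95% in development runs;
* independent Gaussian perturbations of the increments with their
  Poisson-type variances $d_k / S_0(t_k)^2$, truncated at zero.

The 2.5% and 97.5% quantiles of the simulated $RD_h$ form the interval;
the point estimate is computed at $(\hat\beta, d\hat\Lambda)$ and is
seed-invariant.  A mother-level cluster bootstrap
(`rd_cluster_bootstrap`) is provided as a cross-check mode.  In the
stratified design the coefficient draws alone would understate variance —
the effect lives in the baselines — which is why baseline uncertainty is
always included by default.

### Across-subgroup test

The reported "test for different effect across subgroups" is not described
operationally in the source literature; `interaction_test` is a Wald test
on the per-level simulation draws of $RD_h$ (z-test for two levels,
chi-square on $L-1$ contrasts otherwise).  Operating on the draws keeps the
test aligned with the reported estimand rather than with hazard-scale
coefficients; this choice is documented, not asserted as the original
method.

## The synthetic registry

`generator_params()` defaults *are* the study conditions:

| quantity | default | source of the value |
|---|---|---|
| birth window | 1981-01-01 – 1987-12-31 | cohort definition |
| births/day | 145 (≈371k births) | registry cohort size |
| births per mother | 75% / 23% / 2% for 1/2/3 | ≈1.27 births/mother |
| partnered / below-mean income | 84.6% / 45.2% | population table |
| family education low/mid/high/missing | 21.4/47.2/29.9/1.5% | population table |
| low birthweight | 5% | population table (rows transposed there; 94% low would contradict any national birth cohort) |
| leave baseline / noise SD | 98 d (14 weeks) / 20 d | entitlement; day-level spread |
| entitlement extra × take-up | 39.96 d × 0.822 = 32.85 d jump | first-stage estimate and take-up share |
| control 30-y cumulative incidence | 59.5 / 1000 | reported control value |
| risk differences 5…30 y | 2.4, 2.5, 2.0, 2.3, 1.8, 2.0 / 1000 | reported horizon estimates; 30-y value from 59.5−57.5 |
| emigration / death rates | 0.00176 / 0.00138 per p-y | ≈18k emigrations, ≈14k deaths over 10.3M p-y |
| administrative censoring | 2017-12-31 | registry cut-off |

The baseline hazard is piecewise-constant on 5-year intervals — flexible
enough to mimic the steep early post-partum rise, and analytically
invertible for sampling.  The control rates are calibrated so that
cumulative incidence passes through 2.0% at 5 years and 59.5/1000 at 30
years; the intermediate points (3.0, 3.8, 4.6, 5.3%) are a concave
early-rise shape chosen once as plausible for a psychiatric first-diagnosis
process, since only the endpoints are reported.  The eligible stratum gets
its own rates so that $F_c(h) - F_t(h)$ equals the planted risk difference
at *every* horizon simultaneously — a single proportional hazard ratio
could not plant all six.  `calibrate_hazard_ratio` provides the
closed-form single-horizon version,
$HR = \log(1-F_t(h))/\log(1-F_c(h))$, used e.g. to plant subgroup-specific
effects.

What the generator deliberately does **not** emulate: benefit amounts and
the DKK cap, paternal leave sharing, birth seasonality, within-mother
outcome correlation (a `mother_frailty_sd` knob exists but defaults to 0),
and covariate-outcome confounding (prognostic `covariate_log_hr` defaults
to zero so that planted marginal incidences are exact).  Passing recovery
tests therefore shows that the estimator is consistent and its intervals
calibrated under the design's assumptions — not that those assumptions
hold in the Danish registries.

Leave noise is Gaussian truncated at zero; records before 1984-01-01 are
flagged leave-unobserved because the income registry records leave only
from 1984, which is also why the first-stage window is
1 February – 31 May 1984.

## Take-up estimation

"Took up additional leave" has no operational definition in the source.  A
threshold rule (post-cut-off leave exceeding the pre-cut-off prediction by
half the 42-day entitlement) undercounts badly when day-level noise is
comparable to the entitlement: with noise SD 20 d the expected threshold
share is ≈0.72 for a true take-up of 0.822.  `takeup_summary` therefore
reports, as its primary estimate, a constrained Gaussian-mixture
deconvolution of the post-cut-off residuals: the non-taker component mean
is anchored at zero (non-takers sit at the pre-cut-off predicted level by
construction) and the noise SD is fixed from the pre-side residual spread.
Anchoring removes the flat likelihood ridge that makes the unconstrained
two-component mixture ill-determined at this separation.  The threshold
share is still reported for transparency.

## Numerical and design choices

* **Boundary**: a birth exactly on 26 March 1984 is eligible.
* **Calendar arithmetic**: all conversions use 365.25 days/year; follow-up
  of a record whose event lies beyond the administrative date is censored
  there; same-day events get half a day of follow-up so that $t > 0$.
* **Trend order**: shared $u + u^2$ across strata by default, as the
  design specifies; side-specific trends and orders 0–2 are options
  (`side_specific`, `trend_order`), and the first stage defaults to
  side-specific linear trends, standard sharp-RD practice.
* **Placebo reforms** restrict the window to the true-cut-off side
  containing the placebo date, so genuinely treated births never
  contaminate the placebo contrast.
* **ICD-8→10 transition (1994)**: `split_at_calendar_date` produces
  counting-process episodes with an era indicator; `era_adjusted_fit`
  refits with the indicator as a time-dependent covariate and predicts at
  the era path of a birth at the cut-off.
* **Degenerate inputs** raise errors with context: a stratum without
  events, a side of the cut-off without support, horizons beyond observed
  follow-up, take-up probabilities outside $[0,1]$.
* **Determinism**: every stochastic stage takes a seed; identical
  parameters and seed give byte-identical outputs, and derived stage seeds
  stay below $2^{31}$.

## Scale of the shipped simulations

The tests and the acceptance script run at desk scale: first-stage
recovery uses 200 replicates of ≈18 000 births; outcome recovery 100–150
cohorts of ≈50 000 births with 2 000 simulation draws; subgroup recovery
150 cohorts of ≈60 000 births.  At these sizes the Monte-Carlo SE of the
mean recovered 5-year risk difference is ≈0.15 per 1000 and of the
take-up share ≈0.5 percentage points.  Reference scale (371k births,
100 000 draws) is a parameter change (`mean_births_per_day = 145`,
`n_sims = 1e5`).

## Known limitations

* Death and emigration are treated as independent censoring, not competing
  risks, matching the source analysis; cumulative incidences are slightly
  overestimated relative to a competing-risks decomposition.
* The first-order propagation of coefficient uncertainty into the Breslow
  baselines is an approximation; the cluster bootstrap is the exact (but
  expensive) alternative.
* The generator draws covariates independently of the outcome by default,
  so covariate adjustment beyond the RD trend is not exercised by the
  recovery suite.
* Subgroup analyses report unadjusted interaction p-values; no
  multiple-testing correction is applied, as in the source analysis.
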