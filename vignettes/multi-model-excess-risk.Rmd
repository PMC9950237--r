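---
title: "Multi-model inference for solid-cancer excess risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-model inference for solid-cancer excess risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the statistics it implements:
the grouped-Poisson likelihood behind every fit, the published model
forms and how ambiguities in their printed notation were resolved, the
Monte-Carlo uncertainty machinery, the information-criterion averaging,
and the synthetic-data generator that the test suite relies on.

## The likelihood

All models are Poisson regressions for grouped cohort data. A cohort
table has one row per stratum cell with person-years `pyr` and a case
count `cases`; the expected count in a cell is `pyr * lambda(cell)`, and
the full negative log-likelihood is

```
sum over cells [ mu - y*log(mu) + log(y!) ],   mu = pyr * lambda
```

Cells with `pyr = 0` are kept in the table (so row counts match source
files) but flagged and excluded from every likelihood. The `log(y!)`
constant is retained, so absolute AIC/BIC values are on the full-likelihood
scale; it cancels in all weight and delta computations, which is why the
model-averaging layer works exclusively with IC *differences*.

The rate composes a baseline with an excess, additively for EAR models
(`lambda = lambda0 + EAR`) and multiplicatively for ERR models
(`lambda = lambda0 * (1 + ERR)`). During optimisation a parameter vector
can compose to a non-positive rate (for instance `1 + ERR < 0` at high
dose); this is treated as an infeasible-parameter condition: the exported
`neg_log_likelihood()` returns `+Inf` with a flag, while the internal
optimiser objective returns a large finite penalty that grows with the
amount of infeasibility so line searches are steered back into the
feasible region rather than crashing. Rejection keeps all coefficients on
their natural published scales; no reparameterisation is applied.

## Model forms and notational decisions

The registry covers the BEIR VII phase 2 linear model, Grant, Ozasa and
Preston models in L and LQ dose response, the INWORKS-Leuraud L/LQ
models, the UNSCEAR L/LQ models and the Little
linear-quadratic-exponential (LQE) model, each in an ERR and an EAR
family with its published baseline. Where the printed notation is
ambiguous the package fixes a convention and documents it:

* **Sex coding.** `s = -1` for men, `+1` for women, in the `(1 + sigma*s)`
  factor and in every sex-interaction baseline term. The symmetric coding
  is the convention of the LSS literature and keeps `(1 + sigma*s)`
  positive for `|sigma| < 1`.
* **Threshold subscripts** are multiplicative indicators closed exactly
  as printed: `e > 30` and `e > 50` strict, the Grant spline knot
  `a > 70` strict, the absolute-rate spline knots `a >= 40` and
  `a >= 70` inclusive.
* **INWORKS attained-age bands.** The printed bands (`a < 60`,
  `60 < a < 80`, `a > 80`) leave the boundaries unassigned; the package
  assigns boundaries to the lower band (`nu1` for `a <= 60`, `nu2` for
  `60 < a <= 80`). The resulting discontinuities are in attained age
  only; every form is continuous in dose.
* **BEIR's sex-specific slope** `alpha_s` is implemented as two free
  scalars (`alpha_m`, `alpha_f`). The published symbol-group count (3)
  is retained on the model object as `n_literal_excess` next to the
  implemented scalar count.
* **City-specific intercepts.** The absolute-rate baselines of BEIR and
  Ozasa open with a sex-specific city term; it is implemented as four
  sex-by-city intercepts, the natural reading of "city-specific
  effects". The `c NIC` term of the Grant/Preston baselines is one
  coefficient per city multiplying the not-in-city indicator.
* **UNSCEAR baseline.** Implemented with coefficients `k0..k22` exactly
  as the printed expression (23 scalars) even though the published
  coefficient count says 22; the printed formula wins. Its
  time-since-exposure terms require `a > e` strictly; queries at
  `a = e` raise a domain error rather than silently extrapolating.
* **Logarithms** are natural throughout (the printed forms mix `log` and
  `ln`; nothing suggests base 10).
* **Preston dose truncation.** The Preston models declare a 4 Gy dose
  cap on their model object; the fitting layer applies it automatically,
  assigning the cap to cells with larger doses.

## Fitting

Parametric baselines are log-linear in their coefficients, so
`rate = exp(X k)` for a design matrix `X`; they are fitted jointly with
the excess block. The optimiser start is informed by a Poisson GLM of
the baseline alone (offset `log(pyr)`), with the dose slope started at a
small positive value; additional starts are deterministic jitters, so
fits are exactly reproducible with no seed. Optimisation is BFGS with
numerical gradients, relative tolerance 1e-10, and up to three restart
rounds — restarting resets BFGS's curvature approximation, which
measurably polishes optima in the nearly flat directions of weakly
identified modifiers. Per-parameter scaling (`parscale`) puts the EAR
dose coefficients, naturally of order 1e-3 per person-year, on the same
footing as the modifiers.

Stratified baselines (the ERR variants of BEIR, Ozasa and INWORKS) are
never optimised directly: for fixed excess parameters each stratum's
rate has the closed conditional MLE `sum(y) / sum(pyr * (1 + ERR))`, so
the excess block is optimised against the profiled likelihood and the
strata (500-odd of them) cost nothing. Zero-case strata sit at the
boundary `lambda0 = 0` and contribute only their expected counts. For
completeness the additive analogue is available through one-dimensional
root finding on the stratum score equation, though no registered EAR
model has a stratified baseline. Each stratum still counts as one
parameter in AIC (`2k - 2lnL`) and BIC (`k ln(n_cells) - 2lnL`, with
`n` the number of likelihood cells — the grouped-data convention).

The covariance is the inverse of a symmetric central-difference Hessian.
The base step is 1e-4 relative (1e-4 absolute below magnitude 1); where
a direction's second difference falls below floating-point noise the
step widens geometrically (to at most 0.5) so that near-flat curvatures
are measured at the scale where they exist instead of being read from
rounding error. Inversion happens on the correlation scale so that the
very different magnitudes of baseline and modifier curvatures do not
masquerade as singularity; a condition number above 1e12 after scaling
marks the covariance unavailable, and the Monte-Carlo layer then refuses
to sample rather than fabricating intervals.

Two fitting strategies mirror the two published analyses: *variable
baseline* (each model keeps its own published baseline) and *constant
baseline* (the AIC-best parametric baseline, selected by fitting each
candidate baseline alone with zero excess, is refitted jointly with
every excess form). The joint refit — rather than freezing the baseline
coefficients at their baseline-only MLE — was chosen because frozen
coefficients could not produce the distinct per-model IC values the
constant-baseline comparison is meant to expose. In constant-baseline
mode, models whose excess forms are identical (the Grant, Ozasa and
Preston forms share one parametrisation) collapse to a single
representative before weighting so no form is double-counted.

Fits of the full forms to *null-excess* data deserve a caveat: when the
dose slope is essentially zero, its multiplicative modifiers are
unidentified (a Davies-type problem) and Wald machinery for the full
block is ill-posed. `fit_risk_model()` therefore supports Epicure-style
fixing (`fixed = c(tau = 0, ...)`), and the package's null-recovery
simulations test the slope with the modifiers held at zero.

The LQE plausibility screen is applied before model averaging: a fitted
LQE model with negative quadratic coefficient and positive exponential
coefficient describes an excess risk that collapses at high dose and is
excluded, with the signs reported; the rule is scoped to that model
only.

## Monte-Carlo uncertainty

Excess-risk CIs come from sampling coefficient vectors from
`N(theta_hat, Sigma_hat)` over the excess block (the coefficients that
define the excess risk) and evaluating the excess at each query. The
percentile convention, used identically everywhere, is the
left-continuous inverse of the (weighted) empirical CDF with no
interpolation: the p-quantile is the smallest value whose cumulative
weight reaches p. With equal weights this is the `ceil(n*p)`-th order
statistic; the worked mixture example — values {1,2,3,4} carrying total
weight 0.5 pooled with {10,20} carrying 0.5 — has weighted median 4.
Using one convention for single-model and composite intervals makes a
weight-1 composite reproduce the single-model interval bit for bit.
Negative excess realisations are retained, not truncated: the interval
describes the sampled estimator. Realisation counts, repeats and seeds
derive deterministically from a master seed (a Lehmer step keeps derived
seeds within 32-bit range), so any single ensemble can be re-run in
isolation.

The convergence study quantifies how the CI-width estimator stabilises:
for each realisation count N in {5, 10, 20, 50, 100, 200, 500, 1000,
2000, 5000, 10000} it runs six independent ensembles and reports the
mean width, the repeat-to-repeat standard deviation, and the relative
uncertainty `t_factor * sd / sqrt(n_repeats) / mean` — the
small-sample-corrected standard error of the mean width relative to the
width, with `t_factor = 2.45` (the 97.5% t-quantile associated with six
repeats) kept configurable rather than re-derived, since its degrees of
freedom are not uniquely determined by the printed value.
`choose_n_realisations()` scans the table for the smallest N meeting a
target (default 5%); the package default of 1000 realisations comes from
exactly this analysis, and the study's corrected sd scales as `N^(-1/2)`
as Monte-Carlo theory requires.

## Model averaging

`ic_weights()` implements the normalized-exponential weighting above,
identically for AIC and BIC; weights are invariant to adding a constant
to every IC, which the tests check to 1e-12. ERR and EAR families, and
variable- and constant-baseline analyses, always carry separate weight
sets. `prune_weights()` drops models below a threshold (default 0.01)
and renormalizes, matching the practice of reporting only
non-negligible contributors. The composite risk is the weighted sum of
per-model risks (convex, hence always inside the envelope of the
contributing models); the composite CI assigns each realisation of
model i mass `w_i / n_i` and takes weighted percentiles of the pooled
mixture — a deterministic mass-weighting rather than resampling, so the
result is exactly reproducible. Models excluded by the plausibility
screen or by non-convergence are removed before weighting.

## The synthetic cohort generator

The generator emulates the grouped structure of the LSS solid-cancer
incidence file: a grid over 2 cities x 2 sexes x dose categories x
age-at-exposure categories x attained-age categories, a not-in-city
block at zero dose, and a shielded-kerma > 4 Gy split inside the top
dose category. Its defaults are one fixed choice of LSS-like conditions:

* dose grid: 0 plus 7 log-spaced values from 0.05 to 4 Gy — most
  person-years at low dose, as in the cohort;
* age grids: exposure-age midpoints 5–75 and attained-age midpoints
  15–95 in 10-year steps, with `a > e`;
* 5e6 total person-years, allocated proportionally to
  `exp(-0.02 * (a - e)) * exp(-2 * dose)` — an invented allocation law
  (no person-year distribution is published) reproducing the
  qualitative features that late attained ages and high doses carry few
  person-years;
* 20% of person-years in the not-in-city block; 2% of the top dose
  category flagged kerma > 4 Gy;
* birth year derived as 1945 minus age at exposure;
* true model GrantL (ERR) with `alpha = 0.5` per Gy (a sex-averaged ERR
  of 0.5 at 1 Gy, women above men via `sigma = 0.3`), `tau = -0.2` per
  decade, `nu = -1.5`, `phi = -0.5`, and a Grant-form baseline near
  1e-2 per person-year at age 70 rising steeply with age.

Counts are independent Poisson draws from `pyr * lambda` under the true
model, with one explicit RNG stream per table; `perturb_cohort()`
redraws counts from the stored expectations (a parametric bootstrap of
the data layer). The generator records the truth, so recovery tests can
compare Wald intervals against known coefficients.

What the generator does *not* emulate: migration and loss to follow-up,
competing mortality, dosimetry error, smoking and other lifestyle
covariates, and the real file's person-year margins. Passing recovery
tests therefore demonstrate the estimator's correctness under the
model's own assumptions, not robustness to the misspecifications real
cohort data carry.

## Problem sizes in the test suite

The suite favours cohorts of a few hundred cells with 1e7 person-years:
large enough that Wald asymptotics hold (the coverage study uses 200
parametric-bootstrap replicates; the null screen 100), small enough that
the full suite runs in a few minutes. The study-level test runs four
models under both baseline strategies with 200 MC realisations; the
convergence study uses the full ladder up to 10^4 realisations, which
costs seconds because ensembles are cheap once a model is fitted.

## Known limitations

* Absolute AIC/BIC values are on the full Poisson-likelihood scale and
  are not comparable to software reporting deviance-based criteria;
  only differences and weights are.
* Wald/MC intervals inherit the asymptotic-normal approximation; no
  profile-likelihood intervals are provided.
* Mixing stratified and parametric baselines inside one ERR weight set
  penalises the stratified models heavily (each stratum counts as a
  parameter); that is a property of the criteria, not of the
  implementation, and the constant-baseline strategy exists precisely
  to compare excess forms on an equal-baseline footing.
* The shipped lssinc07 column mapping is a best effort for a file whose
  layout is not under the package's control; verify it against the
  downloaded file before use.
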