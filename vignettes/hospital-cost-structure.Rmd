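---
title: "Methods: translog cost systems, scale economies and chain economies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translog cost systems, scale economies and chain economies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainscale)
```

## The cost system

`chainscale` models a hospital's total cost (excluding physician cost,
which in the Dutch institutional setting is funded separately and offers
no substitution margin against other personnel) as a function of four
service volumes and six input prices.  Cost-minimizing behavior is
assumed: hospitals face exogenous demand (patients choose the hospital)
and exogenous prices, and must meet budgets, so the dual cost function
is the natural representation of technology.

The functional form is a translog — a second-order log-polynomial that
imposes no substitution structure a priori — augmented with three
blocks:

* **year effects**, additive shifts `d_t` with the first sample year as
  the zero base, carrying all non-price time variation (technology,
  regulation);
* **trend–price interactions** `t · τ_i ŵ_i`, the only trend terms in
  the specification, letting input-demand patterns drift over time;
* **hedonic case-mix interactions** `ŷ_adm · θ_k z_k`: six hospital
  characteristics (share of surgery/orthopedics, psychiatric beds and
  IC beds per 1000 admissions, expected length of stay, neurosurgery
  and cardiothoracic shares) interacted with log admissions, crediting
  hospitals with a heavier case mix.  The interaction form — rather
  than re-weighting admissions before taking logs — is chosen because
  it keeps the hedonic adjustment linear in estimable coefficients and
  matches the coefficient layout of the published system the package
  ships as a fixture.

Every variable is standardized at its sample arithmetic mean before
estimation (`normalization_point()`, frozen and stored with each fit so
counterfactuals reuse the same means).  This makes first-order
coefficients directly interpretable: at the mean point each `b_m` *is*
the cost elasticity of service `m` and each `g_i` *is* input `i`'s
predicted cost share.

Hedonic characteristics enter centered at their means (not logged —
several are legitimately zero), so the mean-point admissions elasticity
equals `b_adm` exactly.

**Trend units.** The trend is linear in calendar year and zero in the
first sample year, measured in *decades*.  The unit matters only for
interpreting `τ`: with the packaged coefficient fixture, a decades
trend keeps all six predicted shares positive over a 2003–2011 panel,
whereas a raw-years trend would drive the material share negative
within a few years — incompatible with the regularity the source system
reports.  This is the package's convention and is applied consistently
in generation and estimation.

## Share equations and estimation

By Shephard's lemma the cost share of input `i` is the derivative of
log cost with respect to `log w_i`:

`s_i = g_i + Σ_j G_ij ŵ_j + Σ_m d_mi ŷ_m + τ_i t.`

The estimator (`fit_system()`) stacks the cost equation and the share
equations and minimizes a generalized distance with cross-equation
correlated Gaussian disturbances — iterated feasible GLS, the standard
realization of a minimum-distance/SUR estimator:

1. symmetry (`B`, `G`) and linear price homogeneity (`Σg = 1`, zero row
   sums of `G` and `δ`, `Στ = 0`) are imposed *exactly* by
   reparameterization: the capital column of every price block is an
   affine function of the free parameters, never a penalty;
2. observed shares sum to one, so the six share disturbances have a
   singular covariance; one share equation is dropped (capital by
   default — the smallest share variance).  At convergence the iterated
   estimator is the Gaussian ML of the system, which is invariant to
   the dropped equation; the test suite verifies invariance to `1e-6`
   across all six choices;
3. iterations start at the pooled least-squares solution, re-estimate
   the residual covariance, and stop when the largest coefficient
   change falls below `1e-8` (at most 500 iterations).  The
   concentrated Gaussian criterion is tracked and is non-increasing.
   An exactly fitting system (zero residuals) is detected and returned
   from the first solve, since the residual covariance is then
   singular by construction;
4. the coefficient covariance is ML-style (no degrees-of-freedom
   correction), from the information matrix at the converged weights.
   On synthetic data it agrees with a 200-draw nonparametric bootstrap
   within Monte-Carlo noise (test suite).

Identification failures (zero-variance or collinear regressors —
including the intrinsic collinearity of trend–price with first-order
price terms in single-year samples) surface as an explicit
"not identified" error, not as a silent near-singular solve.

**Two-stage procedure.** ER volumes are observed only for a subsample
(in the emulated design, 249 of 682 hospital-years).  `two_stage_fit()`
first estimates the three-service system on all observations, then
re-estimates on the ER subsample with ER visits added, freeing the
intercept, all first-order output terms, the own-quadratic output terms
and all output–price interactions, while fixing the price (`g`, `G`,
`τ`), year-effect, hedonic and cross-output second-order blocks at
their stage-1 values (ER cross terms at zero).  Fixing the price block
presumes prices and services are uncorrelated, which holds by
construction for region/year-driven price proxies.  The carried blocks
are bit-for-bit identical across stages (tested).  Monte-Carlo runs in
the test suite show the procedure recovers a true ER coefficient well
within its sampling spread, with a small finite bias traceable to the
stage-1 year effects being estimated without the ER terms.

## Input price construction

The three price constructions mirror standard practice for this kind of
panel:

* **labor** (`labor_price_proxy()`): observed unit values (cost per
  FTE) are partly endogenous, so each category's unit value is
  regressed on region and year indicator sets (via `stats::lm`) and the
  fitted values — varying only by region × year — serve as exogenous
  market-price proxies;
* **materials** (`material_price_index()`): no natural quantity unit
  exists, so the price is one in the base year and follows the national
  CPI, with no regional variation;
* **capital** (`capital_volume_index()`, `capital_price()`): an
  implicit price, capital cost over a volume index.  The index is a
  weighted aggregate of beds, IC beds, radiotherapist counts (equipment
  proxy) and operating theatres, with weights from an intercept-free
  least-squares regression of capital cost on the components (an
  intercept would assign capital volume to a hospital with no capital),
  rescaled to mean one so the capital price is on the cost scale at the
  mean hospital.  Collinear components are dropped with a warning and
  weight zero.

## Scale measures

All incremental and marginal quantities are computed in cost *levels*
(euros), converting from the standardized log surface with the stored
mean cost: `C = C̄ exp(log ĉ)`.

* `overall_scale_elasticity()` computes `v = [Σ_m e_m]⁻¹` and
  cross-checks the equivalent total-cost-over-weighted-marginal-cost
  form to `1e-10` at every call; a non-positive elasticity sum is
  reported as a regularity violation rather than returned.
* `product_scale_elasticity()` replaces zero production — never
  observed; every hospital in the emulated industry runs an ER — by the
  lowest level in the data, `y_min`.  Because the fixed costs of
  `y_min` remain in the counterfactual, the measure is a conservative
  (downward-biased) reading of the zero-production definition.
* `chain_scale_elasticity()` removes the joint volume `y12` from *both*
  services of a sequential pair (symmetrically, following the structure
  of the defining ratio) and divides the average incremental cost by
  `MC1 + MC2` evaluated **at the actual point**, not at the
  counterfactual.  The defining ratio does not pin down the marginal
  cost evaluation point; the actual point is chosen because the
  question asked is marginal — what the *next* joint unit costs at
  current scale — and it makes the `y12 → 0` limit exactly one
  (verified numerically at `y12 = 1e-6 · y1`).
* `conditional_scale_derivative()` differentiates the product-specific
  elasticity numerically (central difference, relative step `1e-4`)
  with respect to a conditioning service, since the analytic derivative
  of a translog-based elasticity ratio is unwieldy.  For
  complementary curvature (positive cross second-order output terms)
  the derivative is negative: increasing returns of one service
  diminish as the other grows.
* `quartile_report()` evaluates every hospital at its own observed
  point and reports Q1/median/Q3 (linear interpolation, `quantile`
  type 7) for marginal costs and all elasticities, excluding (and
  counting) hospitals that fail regularity — any non-positive predicted
  share or cost elasticity.  Default joint volumes: the ER–admission
  chain uses (admission + IC/stroke/CCU disposition shares) × ER
  visits; the ER–outpatient chain uses the outpatient disposition
  share × ER visits; both overridable.

## The synthetic-data generator

`generate_panel()` + `generate_costs()` produce a hospital-year panel
with the statistical structure the analysis assumes, from a known
ground-truth parameter set, so every downstream stage is testable
without the proprietary source data.  Defaults emulate the published
2003–2011 Dutch general-hospital estimation sample:

* 76 hospitals × 9 years thinned to **682 observations** (matching the
  unbalanced panel), **249** of them with ER data;
* service volumes lognormal, hitting the published 2011 cross-section
  means/SDs (admissions 44,767 ± 20,854; outpatients 76,347 ± 29,048;
  other revenues 14,896 ± 10,079; ER visits 24,115 ± 12,771) at the
  reference year, backcast with annual log-growth rates consistent with
  the published 2003→2011 growth (66% admissions, 30% outpatients);
* a log-scale correlation of 0.8 between admissions and ER visits, 0.7
  admissions–outpatients, 0.5 otherwise.  The source reports no joint
  distribution; these are the package's assumptions, configurable in
  `sim_config()`;
* hedonics from the published 2011 moments, constant within hospital;
  ER disposition shares drawn near the published means (no follow-up
  0.35, outpatient 0.27, admission 0.32, IC/stroke/CCU 0.03, other
  hospital 0.01, other 0.03), clamped positive and renormalized to a
  unit simplex per row;
* labor unit values = category base level × region effect × 2.5%/year
  wage growth × noise, with prices then attached through the package's
  own proxy regressions; CPI at 1.8%/year for materials; capital
  components correlated with admissions, costs from known per-unit
  weights, and the implicit capital price from the package's own volume
  index.  Base price levels (e.g. nursing €45,000/FTE-year) are
  assumptions — the source publishes no price levels — and are
  immaterial for any mean-point evaluation;
* standardized log cost = translog surface + Gaussian noise.  By
  default the noise SD is *calibrated* (`calibrate_cost_noise()`) so
  the population cost-equation R² equals 0.98, the goodness of fit the
  source system reports; observed shares = predicted shares +
  mean-zero noise re-projected to sum to one exactly (equivalent to
  dropping one equation in generation, preserving the singular
  covariance the estimator assumes).

Identical configuration and seed give byte-identical panels.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real data: measurement error in volumes,
strategic price setting or price–service correlation, entry/exit and
mergers, serial correlation in the cost disturbance within hospitals,
non-random ER survey response, and outlier contamination.  The
generator is a clean-room twin of the *model*, so estimation tests
demonstrate internal correctness (identification, restriction handling,
convergence), not robustness to misspecification.

## Numerical choices and degenerate inputs

* Convergence: `1e-8` on the maximum coefficient change, 500 iterations
  maximum; seeds affect only synthetic data, never the estimator.
* Exact-fit guard: residual mean square below `1e-18` short-circuits
  the covariance re-estimation (noiseless data would otherwise make the
  weight matrix singular).
* Homogeneity of published fixtures: coefficient tables printed at
  three decimals violate adding-up by up to `1e-3`.  The fixture loader
  re-derives the capital column from the identities
  (`repair_homogeneity()`), changing only capital-column cells by
  ≤ 0.001 — consistent with those cells having been derived then
  rounded — and leaving every anchor coefficient untouched.  Raw
  loading is available with `repair = FALSE`.
* Concavity tolerance: eigenvalues of the substitution matrix up to
  `1e-8` count as non-positive by default (`strict = FALSE` disables
  the slack).  Note that the packaged published parameter set itself
  has one eigenvalue of about `+0.011` at the mean point: its own
  substitution elasticities are all negative there, but the full
  negative semi-definiteness condition fails by one small eigenvalue —
  the "one value slightly greater than zero" pattern its source
  describes for most observations.  The diagnostic reports this
  honestly rather than absorbing it into the tolerance.
* Degenerate inputs: non-positive outputs or prices raise domain errors
  naming the offending field; `y_min` and `y12` bound violations raise
  instructive errors; a finite-difference step crossing the `y_min`
  bound is refused.

## Problem sizes used in the test suite

Estimation and Monte-Carlo tests run at the emulated design size
(n = 682, 50 replicates for recovery; 200 bootstrap draws at n = 600
for the SE comparison) and complete in well under a minute each; these
sizes were chosen as the smallest at which the sampling-theory
comparisons are sharp.  Oracle-equivalence checks use 100 random
evaluation points at tolerance `1e-6` against central finite
differences, and a term-by-term summation oracle at `1e-12`.

## Known limitations

* No quality-of-care or geographic-access dimension: closing an ER
  shifts travel costs to patients; the cost function cannot see this.
* No physician costs, per the institutional setting of the emulated
  system.
* No stochastic-frontier inefficiency term and no endogeneity
  instrumentation beyond the price-proxy construction.
* Confidence intervals for elasticities are not computed analytically
  (no delta method); `bootstrap_fit()` provides the resampling hook.
* The product-specific measure with `y_min` substitution is a lower
  bound on the zero-production definition; comparisons across services
  with very different `y_min/y` ratios should be made with care.
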