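---
title: "Methods: mixture-design optimization and storage degradation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixture-design optimization and storage degradation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lassikin)
```

This vignette documents the statistical methods implemented in `lassikin`,
the conventions and defaults they use, and the design choices made where
more than one reasonable convention exists.

## The mixture stage

### Region and coding

A formulation study varies `q` ingredient amounts inside a box
`[L_i, U_i]` subject to a fixed total (ingredients held constant across
runs, such as sugar or a stabilizer, sit outside the mixture). The packaged
study region (`lassi_design_spec()`) has three components — microgreen
juice 5–9.5 %, dahi 60–64.5 %, water 15–19.5 % — summing to 84.5 %.

All modeling happens in **L-pseudo-component coding**,

$$x_i' = \frac{x_i - L_i}{\mathrm{total} - \sum_j L_j},$$

which maps the constrained region onto the unit simplex
(`to_pseudo()` / `from_pseudo()`, exact inverses to machine precision).
This coding choice is not cosmetic: the packaged published coefficient
tables only reproduce the published predictions at the optimum when
evaluated in L-pseudo coordinates, whereas actual-percentage coding does
not. The package therefore treats L-pseudo coding as the coding of record
for all coefficient tables it ships, and the acceptance tests verify the
reproduction for the five most precisely printed responses at 0.05 %
relative tolerance (the coefficients are printed to 3–4 significant
figures, which is what limits the agreement).

### Scheffé polynomials and fit statistics

Scheffé mixture polynomials are intercept-free; for three components the
special cubic has seven terms `A, B, C, AB, AC, BC, ABC`
(`scheffe_terms()`). `fit_scheffe()` solves the least-squares problem by QR
factorization and fails loudly on rank deficiency (naming the collinear
terms) or on fewer runs than terms.

Because the proportions sum to one, the uncorrected (through-the-origin)
R² of any such model is trivially close to 1. All adequacy statistics are
therefore computed on the **mean-corrected** total sum of squares:

* `r2 = 1 - SSE/SStot`, `adjusted_r2 = 1 - (SSE/(n-p))/(SStot/(n-1))`;
* `predicted_r2 = 1 - PRESS/SStot` with PRESS from the leave-one-out
  hat-matrix identity `e_i/(1-h_i)` (exact for OLS, no refitting);
* `root_mse = sqrt(SSE/(n-p))` and `cv_percent = 100·root_mse/mean(y)`;
* `adequate_precision = (max ŷ - min ŷ)/sqrt(p·MSE/n)`;
* `model_f = (SSmodel/(p-1))/MSE` on mean-corrected totals;
* when the design contains replicated runs (the packaged 17-run design has
  five replicate pairs), a pure-error/lack-of-fit F decomposition is added.

These are the standard response-surface definitions; they reproduce the
magnitude and pattern of the published fit-statistics table (e.g. the
flavonoid response refits with R² ≈ 0.996 against a printed 0.9960, and a
CV % within a few percent of the printed value). A constant response makes
R² undefined; it is reported as 0 with a warning rather than failing,
since the coefficients (equal linear terms, zero interactions) are still
well defined.

### D-optimal selection

`d_optimal_select()` maximizes `det(X'X)` of the Scheffé term matrix over
candidate subsets: a greedy build (ridge-regularized so the first,
necessarily singular, steps still rank candidates) followed by Fedorov
point exchanges until no swap improves the determinant. Ties break toward
the first candidate index; candidates are shuffled once under the seed, so
results are reproducible. The exchange history is recorded and is
non-decreasing by construction, which the tests assert, along with
superiority over random subsets of equal size and full rank of the selected
term matrix.

### Desirability optimization

`desirability_goal()` implements the Derringer–Suich ramps (maximize,
minimize, two-sided target, in-range indicator) with a shape exponent
(`weight`) and an integer `importance`; `overall_desirability()` is the
importance-weighted geometric mean, zero whenever any goal scores zero.

`optimize_formulation()` searches the feasible region with a coarse grid
(default 0.5 % in actual units) followed by two ten-fold local grid
refinements around the incumbent. A grid-then-refine search was chosen over
derivative-based methods because the objective is piecewise smooth with
large exactly-zero plateaus (any infeasible ramp zeroes the geometric
mean), where gradient methods stall. The optimizer provably never returns
an infeasible point — candidates are generated inside the region by
construction — and the refinement step bounds the location error at about
step/200 in actual units.

The original study reports an overall desirability of 0.781 for its chosen
optimum, but the goal set behind that number (which responses entered, with
what spans and importances) is in unavailable supplementary material. The
package therefore ships a documented *paper-like* default in its tests
(maximize juice, minimize dahi and water at importance 3, all responses
in-range over their observed spans) and treats 0.781 as context, not a
verifiable target: the tests assert only well-formedness (a feasible
optimum with all scores in `[0, 1]`).

## The stability stage

### Kinetic fits

`fit_order()` fits the linearizing transform of each reaction order by OLS:
`C` vs `t` (order 0), `ln C` vs `t` (order 1), `1/C` vs `t` (order 2).
Conventions:

* **Rate sign.** Quality indices that *increase* in storage (acidity, free
  fatty acids, TBA, microbial counts) have formally negative zero-order
  slopes. The package stores `k` as a magnitude plus a direction flag,
  matching how stability tables print rate constants.
* **R² scale.** R² is computed on the transformed scale — the scale on
  which the model is linear and on which order selection in the
  linear-fit workflow operates.
* **Chi-square.** The reduced residual form `Σ(O-P)²/(n-p)` on the
  original concentration scale, with `p = 2`. Pearson's `Σ(O-P)²/P` was
  rejected because it is scale-fragile for near-zero indices such as TBA
  (values around 0.02).
* **Initial level for half-lives.** `half_life()` takes `c0` explicitly,
  and `stability_report()` defaults it to the *observed day-0 value*, not
  the fitted intercept. This convention exactly reproduces the published
  half-lives for overall acceptability, plate count and FFA; the published
  acidity and TBA half-lives are 1–2 % below any value reconstructible
  from the printed `(C0, k)` pairs (they were presumably computed with
  unrounded rates) and are not used as checks.
* **Order selection.** Highest transformed-scale R² wins; ties break
  toward the lower order. On noiseless synthetic data the true order is
  recovered whenever the dynamic range is appreciable, which the tests
  check for all three orders.

### Temperature models

Three regressions summarize how rate constants respond to temperature
(all are OLS lines, verified against a normal-equations oracle at 1e-12):

* **Arrhenius** (`fit_arrhenius()`): `ln k` on `(1/T - 1/T_ref)` in
  Kelvin, centered at the arithmetic mean of the storage temperatures by
  default, so `k_ref = exp(intercept)` is the rate in the middle of the
  studied range and `Ea = -slope · R` with `R = 8.314` J/(mol K).
* **Eyring** (`fit_eyring()`): `ln(k/T)` on `1/T`;
  `ΔH = -slope · R`, `ΔS = R·(intercept - ln(k_B/h))` with
  `ln(k_B/h) = 23.760`. Rates given per day are converted to per second
  before the intercept decomposition: ΔH is unit-invariant but ΔS is not,
  so the unit choice is recorded on the fit object. Over a narrow
  temperature window the analytic relation `ΔH ≈ Ea - R·T̄` holds, which
  the tests verify at 1 %.
* **Ball** (`fit_ball()`): `log10 D` on `(T - T_ref)` in **Celsius**
  (the model is defined on temperature differences), with `D = ln10/k`,
  `Z = -1/slope` and `D_ref = 10^intercept`.

On the packaged rate table, the recomputed activation energies span the
9–22 kJ/mol band narrated by the study, with overall acceptability the
largest — but the exact printed Ea values are not reproducible from
3-significant-figure rate inputs, so they are checked only at ±5 % and
only for the headline index. The study's printed Z-values (0.114–0.230 °C)
are physically inconsistent with the decade-reduction definition applied
to its own rate constants, which imply Z of tens of degrees; the package
implements the standard definition and treats the printed Z values as
unverifiable (the tests assert only finiteness and the correct sign).

### Shelf life and reports

`shelf_life_to_limit()` inverts each order law for the time to reach a
threshold; the half-change criterion coincides with `half_life()` by
construction (a cross-module identity the tests assert exactly).
`shelf_life_at_temperature()` chains `predict_k()` into the inversion, so
predictions at the fitted reference temperature equal `c0/(2 k_ref)`
exactly, and warmer storage shortens predicted life whenever `Ea > 0`.
A named microbial criterion — `limit = 6` on the log10 cfu/mL scale, the
common ready-to-eat guideline of 10^6 cells/mL — is supported directly.

`stability_report()` assembles the per-(index, temperature) rate table
(all three orders, selected order, half-life) plus per-index
Arrhenius/Eyring/Ball parameters. Temperature models require a **single
shared order per index** (rate constants of different orders live on
different scales), so the report picks the order with the highest mean R²
across temperatures, ties toward the lower order. `write_report()` renders
reports with fixed rounding (k to 4 decimals, R² to 3, times to 2) and
deterministic ordering, so identical inputs give byte-identical files.

## Packaged study tables

`lassi_fixtures()` loads the study's tables from `inst/extdata/` with an
md5 integrity check: the 17-run design with sixteen responses, the sixteen
published special-cubic models and their fit statistics, six storage
series (anthocyanins, phenolics, flavonoids, ascorbic acid, FFA, TBA) at
three temperatures over 15 days, the published rate-constant table, day-0
index levels, and the optimum formulation with predicted and observed
responses. Three data quirks are handled explicitly:

* the storage-temperature grid is stored as 5/15/25 °C throughout (the
  methods text), although one published table labels the middle
  temperature "10";
* two design runs whose printed amounts were rounded to two decimals (and
  so summed to 84.51) are stored de-rounded (61.875/16.875 and
  6.875/16.875) so every run satisfies the 84.5 total exactly;
* the observed ascorbic-acid value at the optimum duplicates the DPPH row
  in the source and conflicts with the day-0 storage narrative; the
  fixture keeps the tabled value with a note column, and no test uses it.

## The synthetic-data generator

`simulate_storage()` emulates the stability study design: Arrhenius-linked
rates across temperatures (default 5/15/25 °C), exact order-law mean
trajectories on the default 0/3/6/9/12/15-day grid, and additive i.i.d.
Gaussian noise per replicate (default 3 replicates). Additive noise on the
concentration scale was chosen because the study's replicate standard
deviations are roughly constant across the storage period rather than
proportional to the level; microbial counts are simulated directly on the
log10 cfu scale, matching how such data are recorded and fitted.
Second-order trajectories that cross zero (an increasing index reaching
its finite-time singularity) are truncated to a small positive floor with
a warning. `simulate_mixture_study()` plays the same role for the mixture
stage, defaulting to the packaged 17-run layout.

`recovery_experiment()` runs repeated simulate-then-fit cycles and reports
bias, RMSE and relative-error quantiles for the activation energy plus
order-selection accuracy. Two noise channels are offered: additive
trajectory noise (the generator default), and lognormal perturbation of
the rates themselves, which isolates the rate-level error that propagates
into Ea.

What passing these tests does **not** show about real data: the generator
draws independent Gaussian errors per time point, so it cannot reveal
sensitivity to correlated drift (instrument or batch effects), to
non-Gaussian spikes (microbial blooms), or to model misspecification such
as biphasic or lag-phase behavior — none of which are in the model family.

## Problem sizes and numerical choices

The test suite and acceptance script use the study's own scales: 17-run
designs, 6-point storage series, 3 temperatures. Monte-Carlo checks use
200 replicates for order-selection accuracy at 1 %-of-range noise and 500
replicates for Ea recovery at 5 % lognormal rate noise (truth taken as the
package's own fit of the published acceptability rates, the study's most
temperature-sensitive index); the full suite runs in a few seconds.
Numerical conventions: sum-to-total and bound checks at 1e-6 with small
negative pseudo values clipped to zero within that slack; round-trip and
feasibility guarantees at 1e-9; regression-vs-oracle agreement at 1e-12;
`k = 0` half-lives and zero-slope Ball fits return `Inf` with a message
rather than erroring; all stochastic code takes explicit seeds.

## Known limitations

* Kinetic fits are unweighted linear fits on transformed scales; no
  nonlinear (untransformed) least squares for orders 1–2, no
  replicate-variance weighting, and no Weibull/biphasic alternatives.
* Only three storage temperatures back the temperature models, so
  curvature in `ln k` vs `1/T` is undetectable by design.
* The desirability optimum is a grid-refined point, not a certified global
  optimizer — adequate for three-component simplices, not for
  high-dimensional mixture-process designs.
* The mixture machinery is written for, and tested on, three components;
  the data structures generalize but higher dimensions are unexercised.
* Shelf-life estimates carry no uncertainty intervals: the packaged tables
  provide means only, with no usable replicate variance model.
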