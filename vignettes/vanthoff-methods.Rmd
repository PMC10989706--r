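---
title: "Free-knot spline analysis of van 't Hoff plots: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-knot spline analysis of van 't Hoff plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vanthoff)
```

## The model

A temperature-gated channel is treated as a two-state system whose
composition is captured by the equilibrium constant `Keq = P/(1 − P)`,
with `P` the open probability. The observable this package fits is
`y = ln Keq` as a function of absolute temperature, with a standard error
per point. The thermodynamics enters through

$$\ln K_{eq}(T) = -\frac{\Delta H(T)}{RT} + \frac{\Delta S(T)}{R},$$

where ΔH and ΔS are themselves temperature dependent whenever the
heat-capacity difference ΔC~p~ between the open and closed states is
nonzero:

$$\Delta H(T) = \Delta H(T_0) + \int_{T_0}^{T}\Delta C_p\,dT',\qquad
  \Delta S(T) = \Delta S(T_0) + \int_{T_0}^{T}\frac{\Delta C_p}{T'}\,dT'.$$

Rather than asserting a parametric form for ΔC~p~(T), the package fits
`ln Keq` with a natural cubic spline `S(x)` in a fit coordinate `x` that is
either the temperature itself or its reciprocal, and differentiates the
spline to obtain the potentials:

$$\Delta G = -RT\,S, \quad
  \Delta H = RT^2\frac{dx}{dT}S', \quad
  \Delta S = \frac{\Delta H - \Delta G}{T},$$

and, as the temperature derivative of ΔH,

$$\Delta C_p = \frac{R\,S''(x)}{T^2} \ \ (x = 1/T), \qquad
  \Delta C_p = 2RT\,S' + RT^2 S'' \ \ (x = T).$$

Direct numerical differentiation of noisy points would amplify the noise;
a twice continuously differentiable spline is the minimal-order smooth
interpolating family whose second derivative — and hence ΔC~p~ — is still
continuous. The ΔC~p~ formulas above are the product-rule reading of the
derivative of ΔH(T); they make ΔC~p~ = dΔH/dT hold exactly, which the test
suite verifies against central finite differences of ΔH on a fine grid.

Both fit coordinates are always scanned. On a physiological window such as
283–323 K, `1/T` is so close to an affine function of `T` that a linear and
a reciprocal trend of comparable slope differ by less than a typical error
bar; the data cannot tell the scales apart, and the selected scale is a
modelling convention, not a finding. The full candidate table is therefore
always retained in reports.

## Fitting and model selection

A spline with `N` intervals has `N + 1` knots. The edge knots are pinned at
the smallest and largest data coordinate (nothing outside the data range is
ever evaluated during fitting; evaluation outside the domain is an error,
not an extrapolation). The free parameters are the `N − 1` interior knot
positions and the `N + 1` knot values — `2N` in total. The fit minimizes
the error-weighted residual sum of squares χ².

Two structural facts shape the optimizer:

* The spline is **linear in the knot values**. For any candidate set of
  interior positions the optimal values are an exact weighted
  least-squares solve in the cardinal natural-spline basis (variable
  projection). The numerical optimizer therefore only searches the
  `N − 1`-dimensional position space, where free-knot problems are known
  to be multimodal; each candidate position set is scored at its exactly
  optimal values. The optimum of the profiled objective is the optimum
  over all `2N` parameters.
* **Ordering is enforced by reparameterization**, not penalties: positions
  are generated from unconstrained parameters through softmax gap weights
  with a minimum separation of `1e-3` of the data range, so every iterate
  is feasible and the interpolation problem stays well conditioned.

Each candidate `(N, scale)` is optimized from `multistart` (default 10)
starts: the first places interior knots at equally spaced positions, the
rest jitter it with a seeded RNG, and one extra start refines the best fit
with one interval fewer by inserting a knot at the midpoint of its widest
gap. Knot insertion reproduces the previous function exactly (uniqueness of
the natural interpolant), so the attainable χ² is non-increasing in `N` by
construction — a property the suite asserts.

Model selection uses
`BIC = χ²min + 2N ln(n)` with `n` the number of data points, interpreting
χ² as a Gaussian negative log-likelihood. Ties within `1e-6` are broken
toward fewer knots (parsimony), then toward the reciprocal scale (the van
't Hoff convention). When no standard errors are supplied the fit uses unit
weights and flags every comparison as relative-only, since the absolute
BIC scale is then meaningless.

## Error propagation from replicates

When the input is replicate open probabilities, each temperature with
`N_m ≥ 2` replicates contributes `y_m = ln(P̄/(1 − P̄))` with the
delta-method standard error
`σ_m = sqrt((1/N_m)(1/(P̄ − P̄²))² σ̃²)`, `σ̃²` the unbiased sample
variance. Temperatures with a single replicate are rejected rather than
imputed. Because macroscopic currents carry non-gating variability where
channels are nearly always closed or open, mean probabilities outside
`(0.01, 0.99)` are dropped by default (overridable, every drop warned).

Because `σ_m` is estimated from few replicates, `(y_m − truth)/σ_m` follows
a Student-t distribution with `N_m − 1` degrees of freedom, not a standard
normal: with 5 replicates only ~62.6% of points sit within one standard
error of the truth, approaching the Gaussian 68.3% as replicates grow. The
calibration tests assert the t rates; users averaging few replicates should
read their error bars accordingly.

## The synthetic generator

`two_state_spec()` fixes a ground truth by `T0`, `ΔH(T0)`, `ΔS(T0)` and a
constant ΔC~p~ (closed-form integrals) or an arbitrary ΔC~p~(T) function
(fixed-step trapezoid at 0.01 K). Noise is homoscedastic Gaussian on
`ln Keq`, or Gaussian on replicate open probabilities with out-of-range
replicates redrawn (rejection keeps the replicate mean unbiased; redraw
counts are recorded). This matches the Gaussian-residual likelihood behind
the BIC; it does **not** emulate temperature-correlated drift, rundown,
voltage-protocol artifacts, seal-quality changes or multi-state gating, so
passing recovery tests demonstrate the estimator's statistical behaviour
under the two-state assumptions, not robustness to such artifacts on real
recordings.

The recovery and calibration studies run under fixed conditions chosen
once:

* **Flat-enthalpy recovery**: ΔH = 100 kJ/mol, ΔS = 300 J/(mol·K),
  ΔC~p~ = 0 — magnitudes typical of heat-activated channels, placing the
  gating midpoint near 333 K; 21 points on 283–323 K with σ = 0.05; 50
  seeds. The scan should select the 2-knot model and recover ΔH within a
  few percent.
* **Strong-ΔC~p~ recovery**: ΔC~p~ = −10 kJ/(mol·K) with ΔH(310 K) = 0 and
  ΔS(310 K) = 0, which bends the plot visibly across the same window; the
  scan should select at least 3 knots and recover mid-range ΔC~p~ within
  25%.
* **Scale indistinguishability**: data from the exactly linear trend
  `ln Keq = −30.3 + 0.1 T` (a 4-log-unit span). The reciprocal curve
  matched to it differs by at most 0.08 log units on 283–323 K; the
  noiseless χ² excess of the wrong scale is `0.039/σ²`. For the premise of
  the study — noise dominating that curvature gap — σ must be well above
  0.2; σ = 0.5 is used, a realistic log-odds error for channel data (at
  σ = 0.05 the scales are in fact statistically distinguishable even on
  this narrow window, the miniature analog of widening the temperature
  range by orders of magnitude).

These studies scan `N` up to 4 (the truths need at most 3 knots; the full
default of 8 is exercised elsewhere) and use the default 10 multistarts;
at these sizes one 50-seed study completes in about a minute.

## Q10 comparisons

`Q10 = Keq(T+10K)/Keq(T)` is read off the fitted spline as
`ln Q10(T) = S(x(T+10)) − S(x(T))` and converted to an enthalpy estimate
`ΔH_Q10 = RT² ln(Q10)/10`, anchored at the lower temperature `T` (the
forward-difference convention; mid-point anchoring would change the bias).
For constant ΔH the estimate is exactly `ΔH · T/(T+10)` — about 3% low
near 300 K — and the generalized step argument lets the bias be tracked to
zero; when ΔC~p~ ≠ 0 the discrepancy is unbounded. The acceptance script
recomputes the 3% figure from a fresh fit.

## Numerical choices and degenerate inputs

* Knot second derivatives come from the standard tridiagonal system solved
  by an O(N) Thomas sweep; tests cross-check against a dense Gaussian
  elimination and against base R's natural `splinefun`.
* Minimum knot separation `1e-3` of the range; optimizer convergence at
  relative tolerance `1e-10` on χ²; BIC tie tolerance `1e-6`.
* `N` is only attempted when `n ≥ 2N + 1`, so every candidate keeps at
  least one residual degree of freedom; fewer than 3 points is an error.
* Open probabilities of exactly 0 or 1, non-positive standard errors,
  duplicate temperatures and zero replicate variance are hard errors that
  name the offending rows; nothing is silently dropped except the
  documented `p_bounds` filter, which warns.
* Zero simulation noise floors the recorded standard error at `1e-6` with
  a warning so downstream weighted fits stay defined.
* All randomness (multistart jitter, simulation noise) flows from explicit
  seeds; seeded calls restore the caller's RNG state, and identical seed
  plus configuration reproduces reports byte for byte.

## Known limitations

* Strictly two-state: multi-state gating schemes, voltage dependence and
  kinetics (non-Arrhenius rates) are out of scope.
* Only differences of thermodynamic potentials are identifiable from
  `ln Keq`; absolute heat capacities are not.
* Spline trends beyond the data (flagged by the `constrained` mask, which
  trusts a grid point only when a datum lies within one mean inter-datum
  spacing in the fit coordinate) reflect the functional form, not the
  data, and should not be interpreted.
* Model selection is local-multistart + BIC; there is no global-optimality
  guarantee for the knot positions and no confidence intervals on knots.
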