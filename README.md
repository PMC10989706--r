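# vanthoff

Thermodynamic analysis of van 't Hoff plots with free-knot natural cubic
splines and BIC model selection.

## The problem

Temperature-gated ion channels (TRPV1, TRPV3, TRPM8, ...) are routinely
characterized by measuring the open probability *P* across temperature and
converting it to a two-state equilibrium constant, `Keq = P / (1 − P)`. The
classical analysis plots `ln Keq` against `1/T` and reads the enthalpy and
entropy differences between the open and closed states off a straight line:

```
ln Keq = −ΔH/(R T) + ΔS/R
```

That line is only straight when ΔH and ΔS do not depend on temperature —
i.e. when the heat-capacity difference between the states vanishes,

```
ΔCp(T) = dΔH/dT,   ΔH(T) = ΔH(T0) + ∫ ΔCp dT',   ΔS(T) = ΔS(T0) + ∫ ΔCp/T' dT'.
```

Large conformational changes usually carry a nonzero ΔCp, so forcing a line
through a curved van 't Hoff plot silently mis-estimates every potential.
`vanthoff` instead fits `ln Keq` with a natural cubic spline `S(x)` in either
the linear (`x = T`) or reciprocal (`x = 1/T`) temperature coordinate. The
edge knots are pinned at the data extremes; the interior knot positions and
all knot values are free parameters, optimized by minimizing

```
χ² = Σ ((y_m − S(x_m)) / σ_m)²
```

The knot count `N + 1` and the temperature scale are selected by the
Bayesian information criterion, `BIC = χ²min + 2N ln(n)`, which penalizes
overfitting. Both scales are always scanned because on physiological
temperature spans linear and reciprocal dependences are statistically
indistinguishable. From the selected spline the package extracts

```
ΔG(T) = −R T S(x(T))
ΔH(T) = R T² (dx/dT) S'(x(T))
ΔS(T) = (ΔH − ΔG)/T
ΔCp(T) = R S''(x)/T²              (reciprocal scale)
        = 2RT S'(T) + RT² S''(T)  (linear scale)
```

together with Q10-based enthalpy estimates for comparison with the common
`Q10 = Keq(T+10K)/Keq(T)` analysis. Replicate open probabilities are
converted to `ln Keq` with delta-method error propagation, and a synthetic
two-state generator with known ΔH, ΔS and ΔCp supports calibration and
parameter-recovery checks.

## Worked example

A small synthetic data set (two-state truth: ΔH = 100 kJ/mol, ΔS = 300
J/(mol·K), ΔCp = 0, noise 0.05 on ln Keq) ships with the package:

```r
library(vanthoff)
f <- system.file("extdata", "two_state_synthetic_lnkeq.csv", package = "vanthoff")
s <- read_series(f)
sel <- select_model(s, fit_config(seed = 1))
print(sel)
```

```
van 't Hoff model selection (BIC; smaller is better)
      scale n_intervals n_params  chi2_min      bic converged selected
     linear           1        2 32.817739 38.90678      TRUE
     linear           2        4 14.805604 26.98369      TRUE
     ...
 reciprocal           1        2 16.978749 23.06779      TRUE        *
 reciprocal           2        4 15.325395 27.50348      TRUE
     ...
selected: reciprocal scale, N = 1 intervals (2 knots)
```

The scan correctly lands on the simplest model — a straight line in `1/T`
(2 knots), i.e. constant ΔH and ΔS — and the thermodynamic curves recover
the ground truth to well within the noise:

```r
compute_thermo(sel$fit, t_grid = c(293, 303, 313))
```

```
  T_K dG_J_per_mol dH_J_per_mol TdS_J_per_mol dS_J_per_mol_K dCp_J_per_mol_K constrained
1 293    12164.751     100546.8      88382.06       301.6452               0        TRUE
2 303     9148.298     100546.8      91398.51       301.6452               0        TRUE
3 313     6131.846     100546.8      94414.96       301.6452               0        TRUE
```

ΔH is estimated at 100.5 kJ/mol (truth 100), ΔS at 301.6 J/(mol·K)
(truth 300), and ΔCp is identically zero for a 2-knot reciprocal model. The
Q10 analysis of the same fit illustrates why the finite-difference shortcut
is biased even here:

```r
q10_curve(sel$fit, t_grid = 303)
```

```
  T_K     Q10 dH_Q10_J_per_mol
1 303 3.57909         97334.45
```

`ΔH_Q10` is `T/(T+10) ≈ 0.968` of the fitted ΔH — about 3% low at room
temperature even for a perfectly linear van 't Hoff plot, and arbitrarily
wrong when ΔCp ≠ 0.

The full pipeline (report JSON with the complete BIC table, curves CSV, Q10
CSV, optional plots) is available as `run_fit()` / `run_simulate()` /
`run_q10()`, or from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "vanthoff.R", package="vanthoff"))')" \
    fit --input data.csv --output-dir out --seed 1
```

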