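# scaffoldwave

Simulation and analysis of a multiphase moving-boundary model for engineered
tissue growth in a rigid porous scaffold — for mathematical biologists and
tissue engineers who want to predict whether, and how fast, a seeded cell
population will colonise a scaffold of given porosity, permeability and
interaction pressures.

## The model

The tissue is a three-phase mixture — cells (volume fraction *n*),
extra-cellular liquid (*w*) and an inert scaffold (*s*), with
*n* + *w* + *s* = 1 — on a domain bounded by a moving tissue edge *L*(*t*).
Darcy closures for both fluid phases plus a constitutive cell-phase pressure
Σ(*n*) (contact repulsion diverging at saturation, dispersal pressure ν*n*,
scaffold attraction) reduce the system to a single degenerate
reaction–diffusion equation with a Stefan-type edge condition, in
dimensionless form

```
n_t = ( n φ(n) n_x )_x + n (κ − n),      0 < x < L(t),
L'(t) = − n_x(L, t),                     n(L, t) = 0,
```

where φ(*n*) = Φ(*n*)/Φ(0) is the normalised nonlinear diffusivity built
from the interaction pressure and the viscosity ratio, and

```
κ = 1 − s − r_a/r_m
```

(scaffold porosity minus the apoptosis/mitosis rate ratio) controls
everything: the tissue edge grows **linearly** behind a travelling wave for
κ > 0, **logarithmically** (with universal coefficient 1/√2) for κ = 0, and
**stalls at a stationary front** for κ < 0.

The package provides:

- the constitutive functions and non-dimensionalisation (`sigma_cell`,
  `Phi`, `phi_nd`, `gamma_net`, `nondimensionalise`);
- a boundary-fixed method-of-lines solver for the moving-boundary system
  (`solve_moving_boundary`, `solve_transformed`) with mass audits, front
  diagnostics and a large-time regime classifier (`total_mass`,
  `front_speed`, `edge_gradient`, `classify_regime`);
- the travelling-wave speed *c*(κ, s, μ, η) by phase-plane shooting on the
  heteroclinic connection (`wave_speed_shooting`, `wave_profile`);
- closed-form small-|κ| asymptotics: the cosh-ansatz family and its exact
  implicit front law, the stationary front position, the interior-layer
  profile, and the general-initial-data constant *m*
  (`alpha_beta`, `solve_L_implicit`, `L_infinity`, `n_smallkappa`,
  `interior_layer_f`, `fit_m`);
- an experiment driver and CSV/JSON output with a reproducibility manifest
  (`regime_report`, `write_outputs`), plus a thin command-line front end at
  `inst/cli/scaffoldwave.R`.

## Worked example

```r
library(scaffoldwave)

q <- nondim_params(kappa = 0.3, s = 0.2)     # porosity 0.8, r_a/r_m = 0.5
res <- wave_speed_shooting(q)
res
#> Travelling-wave speed c = 0.23141322 (kappa = 0.3, s = 0.2, mu = 1, eta = 1)
#>   terminal mismatch 0.000947 after 28 bisections; path outcome: reached_floor

tr <- solve_moving_boundary(q, make_ic_quadratic(omega = 0.03),
                            solver_settings())
tr
#> Moving-boundary trajectory (full system): 101 nodes, 201 report times on [0, 50]
#>   kappa = 0.3; L: 1 -> 11.0626; final dL/dt = 0.232

front_speed(tr, c(35, 50))$speed
#> [1] 0.2319606
```

The two routes agree to 0.24%: a scaffold seeded at 3% occupancy develops a
travelling tissue front moving at 0.232 length units per mitosis time. The
regime sweep reproduces the full trichotomy:

```r
regime_report(c(0.3, 0, -0.3))
#>   kappa      regime     L_end     dLdt_end     c_pde c_shooting   c_rel_err
#> 1   0.3      linear 11.062574 2.322127e-01 0.2319606  0.2314132 0.002365423
#> 2   0.0 logarithmic  2.011062 9.653367e-03        NA         NA          NA
#> 3  -0.3  stationary  1.168331 1.305897e-08        NA         NA          NA
```

κ = 0.3 gives a linear front; κ = 0 creeps logarithmically; κ = −0.3 has
already stalled (edge speed ~10⁻⁸) at L ≈ 1.17. The practical message for
scaffold design: porosity must exceed the death/birth ratio, and the front
is fastest when apoptosis is negligible, porosity is high, and the cell
phase is viscous relative to the liquid (μ, η → 0).

## Command line

```sh
Rscript inst/cli/scaffoldwave.R simulate --kappa 0.3 --ic quadratic --out runs
Rscript inst/cli/scaffoldwave.R wavespeed --sweep 0.1,0.3,0.5 --out runs
Rscript inst/cli/scaffoldwave.R asymptotic --kappa -0.001 --A0 0.05 --B0 0.01 --out runs
Rscript inst/cli/scaffoldwave.R regime-report --kappas 0.3,0,-0.3 --out runs
```

Each run writes CSVs plus a JSON manifest from which it can be re-run
bit-reproducibly; parameters may also come from a flat YAML config
(`--config`, see `read_params_config`).

See `vignettes/tissue-growth-model.Rmd` for the full account of the model,
the numerics, and the accuracy limits of the asymptotic expansions.
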