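---
title: "Modeling LCFA-inhibited anaerobic digestion of algal biomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling LCFA-inhibited anaerobic digestion of algal biomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adlcfa)
```

## The process and the model

Anaerobic digestion of lipid-rich microalgae such as *Nannochloropsis salina*
proceeds through three coupled microbial stages: hydrolytic bacteria
(\(X_h\)) solubilize particulate substrate (\(S_p\)) into hydrolysate
(\(S_h\)); acidogens (\(X_v\)) ferment hydrolysate to volatile fatty acids
(\(S_v\)); methanogens (\(X_m\)) convert VFA to methane (\(S_m\)). All pools
are expressed as COD (kg COD/m^3, identically g COD/L), time in days.

Lipid hydrolysis releases long-chain fatty acids (LCFAs), tracked as
\(S_{fa}\): a fraction \(f_{fa}\) of the hydrolysis flux. LCFAs adsorb onto
cell surfaces and inhibit all three groups. Each stage uses Contois kinetics,
where uptake saturates in the substrate-per-biomass ratio,

\[ \rho_i = k_{m,i}\,\frac{S}{K_{s,i} X + S}\, X\, K_i, \]

multiplied by a group-specific non-competitive inhibition factor driven by
the ratio of protective surface (active biomass plus calcium-bound LCFA
equivalent) to LCFA:

\[ K_i \;=\; \frac{K_{i,fa}\, R}{K_{i,fa}\, R + S_{fa}}, \qquad
   R = \frac{a (X_h + X_v + X_m) + b\, S_{Ca}}{S_{fa}}. \]

As printed, this expression is 0/0 at \(S_{fa} = 0\); the package evaluates
the algebraically identical form \(K_{i,fa} C / (K_{i,fa} C + S_{fa}^2)\)
with \(C = a X + b S_{Ca}\), whose limit is 1 — no LCFA means no inhibition.
With LCFA present but no biomass and no calcium the factor is 0. The factor
is increasing in biomass and calcium and decreasing in LCFA, and larger
inhibition constants always give milder inhibition, so
\(K_{h,fa} \ge K_{v,fa} \ge K_{m,fa}\) implies \(K_h \ge K_v \ge K_m\)
state-by-state.

Biomass decays at first order and the decayed COD is recycled into \(S_p\).
Calcium enters as a binding equivalent \(S_{Ca}\): one calcium ion binds two
LCFA molecules, so a molar dose of \(r\) times the LCFA pool contributes
\(S_{Ca} = 2 r \times\) (potential LCFA COD), making the 0.5 mol/mol dose
exactly cover the pool. \(S_{Ca}\) is set at \(t = 0\) and held constant; no
calcium speciation or precipitation chemistry is modeled.

## COD bookkeeping

Two features of the printed equations deserve attention, because the package
reports a mass balance around them (`cod_report()`):

* The LCFA pool is a *tracking* pool: its inflow duplicates part of the
  hydrolysate flux (lipid COD is counted once in \(S_h\) and again in
  \(S_{fa}\)), and its consumption has no product term. \(S_{fa}\) exists to
  drive the inhibition factors and is excluded from the balance.
* Product pools receive the **full** uptake flux while biomass is
  synthesized *in addition* at yield \(Y\); combined with decay recycling,
  the equations act as a small COD pump (source rate
  \(Y_h \rho_p + Y_v \rho_h + Y_m \rho_v\)). The conserved quantity is
  therefore the pool sum minus the time integral of that source, which the
  integrator carries as an auxiliary state (`growth_cod`). Along any
  trajectory this balance is constant to better than 1e-6 relative (in
  practice ~1e-14).

A visible consequence: simulated specific methane production at the
reference parameter values exceeds what a strict COD balance would allow,
and slower digestion (more turnover cycles before day 20) creates slightly
more COD. This is a property of the published equation set, reproduced
verbatim, not of the implementation. It also produces one small
non-monotonicity in the calcium response surface (below).

## Parameters and defaults

Defaults are the study's reference values. Rates in 1/day, inhibition
constants in kg COD/m^3, yields and fractions dimensionless:
`km_p = 10`, `km_h = 20`, `km_fa = 6`, `km_v = 20`; Contois coefficients
`Ks_* = 0.5`; yields `Y_* = 0.05`; decay `kd_h = kd_v = 0.8`,
`kd_m = 0.05`; `f_fa = 0.35` (whole biomass NS1) or `0.11`
(lipid-extracted residue NS2); `Khfa = Kvfa = Kmfa = 5`; inhibition-ratio
weights `a = b = 0.5`.

Experiment construction (`initial_state()`) uses:

* substrate COD density `cod_vs = 2.83` g COD/g VS — back-derived so that
  the potential-LCFA operation reproduces both reported digester LCFA
  concentrations (9.9 and 3.1 g COD/L at 10 g VS/L loading);
* inoculum COD density 1.42 g COD/g VS, active fraction 1;
* an inoculum split of **65/30/5** between hydrolytic bacteria, acidogens
  and methanogens. The assay does not resolve this split, so it is a
  modeling convention: digester communities are dominated by
  hydrolytic/fermentative bacteria while methanogenic archaea are a small
  minority of the biomass. The split matters: with equal thirds,
  methanogenesis (capacity `km_v * X_m`) is never rate-limiting at these
  rate constants, the methane curve becomes insensitive to `km_v`, `Y_m`,
  `kd_m` and the inhibition constants, and the calibrated-parameter
  partition (below) cannot be reproduced. All of these are arguments of
  `inoculum_spec()`;
* methane volume conversion 0.35 L CH4/g COD (STP; 0.395 at 35 °C is a
  documented alternative in `unit_conversions()`).

## Numerical choices

Integration uses deSolve's `lsoda` (stiff-capable, adaptive) with
`rtol = 1e-8`, `atol = 1e-10`, on a compiled C right-hand side; an identical
R-coded RHS is kept for cross-checks, and the test suite verifies the
adaptive path against an independently coded fixed-step RK4 at
`h = 1e-3` day (agreement ~1e-8 relative on cumulative methane over 20
days). States that undershoot zero by less than 1e-10 are clipped; anything
larger is an error. Contois terms evaluate to zero when biomass or substrate
is zero, so the all-zero state is a fixed point.

## Calibration

Eight parameters are estimated from cumulative methane curves —
`km_v`, `Y_m`, `kd_m`, `Khfa`, `Kvfa`, `Kmfa`, `a`, `b` — the rest being
literature values. `fit_params()` runs bound-constrained
Levenberg–Marquardt (minpack.lm) on the stacked residuals of all curves;
default bounds are (0.1x, 10x) the reference values with `a`, `b` confined
to [0, 1]. Fits are deterministic given the start; optional multi-starts
take explicit seeds. Two numerical details matter:

* **Gauge fixing.** Scaling `a`, `b` by a constant and dividing the three
  inhibition constants by the same constant leaves every trajectory exactly
  unchanged — the weight pair is identified only relative to the constants.
  By default the fit imposes `a + b = 1` (the reference values satisfy it)
  and reports both weights; `normalize_weights = FALSE` gives the raw,
  degenerate parameterization.
* **Finite-difference step.** Residuals are ODE solutions whose accuracy is
  near the solver tolerance, so the default machine-precision difference
  step would difference solver noise in weakly identified directions. The
  default control uses `epsfcn = 1e-6` (steps ~1e-3 relative), which makes
  noiseless recovery exact to optimizer precision.

Three residual forms are available (`loss`): plain residuals on the
cumulative curves (default), per-curve max-normalized residuals, and
`relative_increment` — daily increments divided by the simulated increment.
The last is the whitened likelihood when measurement error is multiplicative
on daily gas readings, which is exactly the noise model of the synthetic
generator: on such data, cumulative least squares mis-specifies the
error covariance (increment noise integrates to a random walk) and lets
weakly identified inhibition constants absorb low-frequency noise, while the
relative-increment loss recovers all eight parameters with a few percent
median error. Use it whenever errors grow with the signal.

## Sensitivity screen

`relative_sensitivity()` implements the local relative–relative measure
\(\delta = (\Delta y / y) / (\Delta p / p)\) by central differences at
±50% by default (a one-sided +100% option exists: a −100% perturbation would
zero the parameter). The printed form of this measure in the source
literature is the reciprocal orientation; `reciprocal = TRUE` reports that.

The default output is the **daily cumulative methane curve**, with
\(\delta\) computed day by day and the largest magnitude kept (days below
1e-6 L/L are excluded from the ratio). The end-of-batch volume is available
via `functional = "final"`, but it is a poor screen here: every batch
reaches its plateau within 20 days at the reference values, so the endpoint
sees only the COD-recycle pump (`km_p`, `Y_h`, `kd_h`) and is blind to
rate and inhibition parameters that only shift the curve in time — yet the
curve is what calibration uses. `sensitivity_screen()` evaluates each
parameter across the full experimental grid of the high-lipid substrate
(I/S in {0.1, 0.4, 1.0} × Ca in {0, 0.5, 1, 2}) and takes the maximum
magnitude — a parameter is kept for estimation if it is influential anywhere
in the design space (calcium weight `b` is inert without calcium; `kd_m`
only acts where conversion is incomplete). With threshold 0.1 this
partition places all eight estimated parameters in the high set.

## Synthetic BMP studies

`generate_bmp_study()` emulates the batch campaign: 2 substrates × I/S
{0.1, 0.4, 1.0} × calcium {0, 0.5, 1, 2} at 10 g VS/L, 35 °C, 20 days, one
cumulative methane reading per day. Noise is applied to the **daily
increments** (multiplicative Gaussian, default 5% relative s.d., clipped at
zero and re-cumulated), so curves are non-negative and non-decreasing at any
noise level — measurement error on a gas counter cannot make cumulative gas
shrink. At 5% the clipping is essentially never active and the final volume
is unbiased to <1%. Generation is bit-reproducible from its seed and
restores the caller's RNG state.

What the generator does *not* emulate: correlated day-to-day drift,
temperature or headspace corrections, CO2-scrubbing artifacts, replicate
bottle variance, or structural mismatch between model and data. Passing
recovery tests on these data therefore demonstrates estimator correctness
and identifiability under the model's own assumptions, not robustness to
real-world model error.

## Problem sizes used by the tests

The test suite and the acceptance script run simulation studies sized for a
single CPU: 12-curve studies (2 substrates × 3 I/S × calcium {0, 0.5} —
control plus the stoichiometrically ideal dose) for recovery, 10 replicate
noise seeds, a 5 × 5 response-surface grid, the 24-batch grid for the COD
balance, and one 20,000-step RK4 reference integration.

## Known limitations

* The verbatim equation set creates COD (yield double-count plus decay
  recycling) and double-counts lipid COD in the LCFA tracking pool; the
  balance report quantifies rather than removes this. Absolute SMP values
  are correspondingly high and should be read comparatively.
* One cell of the default 5 × 5 response surface (biomass:LCFA 0.375,
  calcium 0 → 0.5) *decreases* by ~0.2% of the surface range: calcium
  speeds digestion, leaving fewer pump cycles before day 20. The surface is
  otherwise monotone in both axes, and the inoculum axis dominates the
  calcium axis by two orders of magnitude.
* `Kvfa` and `Kmfa` are weakly identified from curves alone when
  methanogen inhibition barely binds; under inoculum-rich conventions their
  recovery error is bounded by the box constraints rather than the data.
* Single lumped VFA pool; no pH, ammonia, hydrogen or VFA speciation; no
  temperature dependence (35 °C only); no gas-phase model.
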