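# adlcfa

Kinetic modeling of long-chain fatty acid (LCFA) inhibition during batch
anaerobic digestion of algal biomass.

Digesting lipid-rich microalgae (e.g. whole *Nannochloropsis salina*, "NS1",
37% lipid) releases LCFAs that adsorb onto microbial cells and slow the whole
process; its lipid-extracted residue ("NS2", 12% lipid) is the low-LCFA
counterpart. This package is for bioprocess modelers who want to simulate,
calibrate and interrogate an eight-pool Contois-kinetics model of that
system in which hydrolysis, acidogenesis and methanogenesis each carry their
own non-competitive inhibition factor

    K_i = K_ifa * R / (K_ifa * R + S_fa),
    R   = (a*(X_h + X_v + X_m) + b*S_Ca) / S_fa,

driven by the ratio of protective surface — active biomass plus the
calcium-bound LCFA equivalent `S_Ca` (1 Ca ion binds 2 LCFAs, so a
0.5 mol/mol dose covers the pool) — to the LCFA concentration `S_fa`. All
pools are COD (kg COD/m^3 = g COD/L), time in days.

The package provides:

* `ad_params()`, `model_state()`, `ad_rhs()`, `simulate_ad()`,
  `cod_report()` — the ODE system (compiled RHS, adaptive stiff solver) with
  per-step inhibition factors and a COD balance report;
* `substrate_ns1()/substrate_ns2()`, `inoculum_spec()`, `batch_config()`,
  `initial_state()`, `potential_lcfa()`, `calcium_equivalent()`,
  `methane_curve()`, `smp()`, `smp_sweep()` — batch experiment setup and
  derived outputs (specific methane production, response surfaces);
* `fit_params()` / `objective_ssq()` — bound-constrained Levenberg–Marquardt
  calibration of the eight estimated parameters against cumulative methane
  curves, with an identifiability gauge (`a + b = 1`) and a whitened
  relative-increment loss;
* `relative_sensitivity()` / `sensitivity_screen()` — the local
  relative–relative sensitivity measure and the screen that partitions
  parameters into fixed vs. estimated sets;
* `generate_bmp_study()` — a seeded synthetic generator of daily cumulative
  biochemical-methane-potential (BMP) curves over the 2-substrate × 3-I/S ×
  4-calcium design, for parameter-recovery studies;
* file I/O for curves, parameter sets, manifests and sweep tables, plus a
  small CLI (`run_cli()`, `inst/cli/adlcfa.R`) with `simulate`, `generate`,
  `fit`, `sensitivity` and `sweep` subcommands.

## Worked example

Simulate the high-lipid substrate at inoculum-to-substrate ratio 0.4 with
the stoichiometrically ideal calcium dose (0.5 mol per mol LCFA):

```r
library(adlcfa)

cfg <- batch_config(loading = 10, is_ratio = 0.4, ca_ratio = 0.5,
                    duration = 20)
potential_lcfa(substrate_ns1(), cfg)
#> [1] 9.905

s0 <- initial_state(substrate_ns1(), inoculum_spec(), cfg)
round(s0, 3)
#>    S_p    S_h    S_v   S_fa    S_m    X_h    X_v    X_m   S_Ca
#> 28.300  0.000  0.000  0.000  0.000  3.692  1.704  0.284  9.905

traj <- simulate_ad(ad_params(), s0, t_end = 20, report_step = 1)
round(traj[c(2, 6, 21), c("time_d", "S_p", "S_fa", "S_m", "K_h", "K_m")], 3)
#>    time_d   S_p  S_fa    S_m   K_h   K_m
#> 2       1 7.169 2.953  7.063 0.806 0.806
#> 6       5 0.022 0.012 37.445 1.000 1.000
#> 21     20 0.380 0.000 38.487 1.000 1.000

smp(methane_curve(traj), loading = 10)   # L CH4 per g VS fed
#> [1] 1.347055

cod_report(traj)
#> COD balance report: 21 time points
#>   initial balance : 33.98 kg COD/m3
#>   max rel. drift  : 3.554805e-15
```

Reading the output: the substrate could liberate 9.9 g COD/L of LCFA (the
reported NS1 value; NS2 gives 3.1). At this inoculum level LCFA peaks near
3 g COD/L on day 1 and pushes every inhibition factor to ~0.8, then is
consumed and inhibition vanishes; cumulative methane (`S_m`, COD units) is
converted to volume with 0.35 L CH4/g COD. The COD balance (pool sum minus
the tracked biomass-synthesis integral) is conserved to machine precision —
see the methods vignette for why the printed equation set needs that
correction term and why absolute SMP values run high.

At a state matching the uninhibited-start worked numbers
(`X_h = X_v = X_m = 1`, `S_fa = 9.9`, no calcium), the three factors are
equal at the shared inhibition constant:

```r
compute_inhibition(ad_params(), model_state(X_h = 1, X_v = 1, X_m = 1,
                                            S_fa = 9.9))
#>    K_h    K_v    K_m
#> 0.0711 0.0711 0.0711
```

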