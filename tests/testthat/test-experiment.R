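test_that("potential LCFA reproduces the two reported digester concentrations
           and is linear in loading and fatty-acid fraction", {
  cfg <- batch_config(loading = 10, is_ratio = 1)
  expect_equal(round(potential_lcfa(substrate_ns1(), cfg), 1), 9.9)
  expect_equal(round(potential_lcfa(substrate_ns2(), cfg), 1), 3.1)
  sub0 <- substrate_spec("none", 0, 10, 10, 80, 90, f_fa = 0)
  expect_equal(potential_lcfa(sub0, cfg), 0)
  # linearity
  s <- substrate_ns1()
  expect_equal(potential_lcfa(s, batch_config(loading = 20, is_ratio = 1)),
               2 * potential_lcfa(s, cfg))
  s2 <- substrate_spec("half", 20, 10, 10, 60, 90, f_fa = s$f_fa / 2)
  expect_equal(potential_lcfa(s2, cfg), potential_lcfa(s, cfg) / 2)
})

test_that("calcium binding equivalent follows the 1 Ca : 2 LCFA stoichiometry", {
  expect_equal(calcium_equivalent(0, 9.9), 0)
  expect_equal(calcium_equivalent(0.5, 9.9), 9.9)
  expect_equal(calcium_equivalent(2, 3.1), 12.4)
  expect_error(calcium_equivalent(-0.5, 9.9), "non-negative")
})

test_that("initial states assemble substrate, inoculum and calcium pools", {
  equal <- inoculum_spec(split = c(X_h = 1/3, X_v = 1/3, X_m = 1/3))
  s0 <- initial_state(substrate_ns1(), equal, batch_config(is_ratio = 1))
  expect_equal(s0[["S_p"]], 28.3)
  expect_equal(unname(s0[c("X_h", "X_v", "X_m")]), rep(14.2 / 3, 3),
               tolerance = 1e-12)
  expect_equal(sum(s0), s0[["S_p"]] + sum(s0[c("X_h", "X_v", "X_m")]))
  # no inoculum, no biomass
  s1 <- initial_state(substrate_ns1(), equal, batch_config(is_ratio = 0))
  expect_equal(unname(s1[c("X_h", "X_v", "X_m")]), c(0, 0, 0))
  # calcium at half the molar dose covers the full LCFA pool
  s2 <- initial_state(substrate_ns1(), equal,
                      batch_config(is_ratio = 1, ca_ratio = 0.5))
  expect_equal(s2[["S_Ca"]],
               potential_lcfa(substrate_ns1(), batch_config(is_ratio = 1)))
  expect_error(inoculum_spec(split = c(0.5, 0.2, 0.2)), "summing to 1")
  expect_error(inoculum_spec(ts = 10, vs = 12), "VS cannot exceed TS")
})

test_that("methane curves convert COD to volume and preserve monotonicity", {
  p <- ad_params()
  s0 <- initial_state(substrate_ns1(), inoculum_spec(),
                      batch_config(is_ratio = 0.4))
  traj <- simulate_ad(p, s0, t_end = 20, report_step = 0.5)
  curve <- methane_curve(traj)
  expect_identical(curve$day, 0:20)
  expect_true(all(diff(curve$cumulative_CH4_L_per_L) >= -1e-9))
  i <- match(7, traj$time_d)
  expect_equal(curve$cumulative_CH4_L_per_L[8], traj$S_m[i] * 0.35)
  # zero trajectory gives a flat zero curve and zero SMP
  z <- methane_curve(simulate_ad(p, model_state(), t_end = 20,
                                 report_step = 1))
  expect_true(all(z$cumulative_CH4_L_per_L == 0))
  expect_equal(smp(z, 10), 0)
  expect_error(smp(curve, 0), "strictly positive")
  # SMP is the final volume over the loading
  expect_equal(smp(curve, 10),
               curve$cumulative_CH4_L_per_L[21] / 10)
})

test_that("a 1x1 sweep equals a single simulation and zero biomass rows
           produce no methane", {
  p <- ad_params()
  inoc <- inoculum_spec()
  sub <- substrate_ns1()
  sw <- smp_sweep(sub, inoc, p, biomass_ratios = 0.717, ca_ratios = 0.5)
  expect_equal(nrow(sw), 1L)
  lcfa <- potential_lcfa(sub, batch_config(is_ratio = 0))
  x <- 0.717 * lcfa * inoc$split
  s0 <- model_state(S_p = 28.3, X_h = x[["X_h"]], X_v = x[["X_v"]],
                    X_m = x[["X_m"]],
                    S_Ca = calcium_equivalent(0.5, lcfa))
  direct <- smp(methane_curve(simulate_ad(p, s0, t_end = 20,
                                          report_step = 1)), 10)
  expect_equal(sw$smp, direct, tolerance = 1e-10)
  sw0 <- smp_sweep(sub, inoc, p, biomass_ratios = 0,
                   ca_ratios = c(0, 1, 2))
  expect_true(all(sw0$smp < 1e-9))
  expect_true(all(sw0$ok))
  expect_error(smp_sweep(sub, inoc, p, biomass_ratios = numeric(0)),
               "non-empty")
})
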