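test_that("the RHS reproduces hand-computed fluxes and trivial zeros", {
  p <- ad_params()
  expect_equal(unname(ad_rhs(p, model_state())), rep(0, 9))
  # substrate without biomass: no flux, no decay
  expect_equal(unname(ad_rhs(p, model_state(S_p = 28.3))), rep(0, 9))
  # hydrolysis-only state: flux = 10 * 28.3/28.8 * 1, hand arithmetic
  d <- ad_rhs(p, model_state(S_p = 28.3, X_h = 1))
  expect_equal(d[["S_p"]], -9.0264, tolerance = 1e-4)
  expect_equal(d[["S_h"]], 9.8264, tolerance = 1e-4)
  expect_equal(d[["S_fa"]], 3.4392, tolerance = 1e-4)
  expect_equal(d[["X_h"]], -0.3087, tolerance = 1e-4)
  expect_equal(d[["S_Ca"]], 0)
  expect_error(ad_rhs(p, c(model_state()[-1], S_p = -1)), "non-negative")
})

test_that("compiled and R right-hand sides integrate identically", {
  p <- ad_params()
  s0 <- initial_state(substrate_ns1(), inoculum_spec(),
                      batch_config(is_ratio = 0.4, ca_ratio = 1))
  t1 <- simulate_ad(p, s0, t_end = 10, report_step = 1)
  t2 <- simulate_ad(p, s0, t_end = 10, report_step = 1, compiled = FALSE)
  expect_equal(as.matrix(t1[-1]), as.matrix(t2[-1]), tolerance = 1e-8)
})

test_that("trajectories are non-negative with non-decreasing methane and
           carry inhibition factors consistent with the states", {
  p <- ad_params()
  s0 <- initial_state(substrate_ns1(), inoculum_spec(),
                      batch_config(is_ratio = 0.1))
  traj <- simulate_ad(p, s0)
  expect_true(all(as.matrix(traj[-1]) >= 0))
  expect_true(all(diff(traj$S_m) >= -1e-8))
  i <- which.max(traj$S_fa)
  expect_equal(traj$K_m[i],
               compute_inhibition(p, unlist(traj[i, c("S_p", "S_h", "S_v",
                 "S_fa", "S_m", "X_h", "X_v", "X_m", "S_Ca")]))[["K_m"]],
               tolerance = 1e-12)
  # all-zero start stays identically zero (and uninhibited: factors at 1)
  z <- simulate_ad(p, model_state(), t_end = 5, report_step = 1)
  state_cols <- c("S_p", "S_h", "S_v", "S_fa", "S_m",
                  "X_h", "X_v", "X_m", "S_Ca", "growth_cod")
  expect_true(all(as.matrix(z[state_cols]) == 0))
  expect_true(all(as.matrix(z[c("K_h", "K_v", "K_m")]) == 1))
})

test_that("reported states do not depend on the reporting step", {
  p <- ad_params()
  s0 <- initial_state(substrate_ns1(), inoculum_spec(), batch_config())
  coarse <- simulate_ad(p, s0, t_end = 10, report_step = 2)
  fine <- simulate_ad(p, s0, t_end = 10, report_step = 0.5)
  shared <- fine[fine$time_d %in% coarse$time_d, ]
  expect_equal(as.matrix(shared), as.matrix(coarse), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("biomass-only startup recycles decay through the particulate pool
           and keeps the COD balance", {
  p <- ad_params()
  s0 <- model_state(X_h = 2, X_v = 1, X_m = 0.5)
  traj <- simulate_ad(p, s0, t_end = 20, report_step = 0.5)
  expect_gt(max(traj$S_p), 0)        # decay feeds S_p
  expect_gt(traj$S_m[nrow(traj)], 0) # and is re-digested to methane
  expect_lt(cod_report(traj)$drift, 1e-6)
})

test_that("the balance report flags a broken decay route and accepts
           quadrature reconstruction", {
  p <- ad_params()
  s0 <- initial_state(substrate_ns1(), inoculum_spec(), batch_config())
  good <- rk4_oracle(p, s0, t_end = 5, h = 1e-3)
  broken <- rk4_oracle(p, s0, t_end = 5, h = 1e-3, recycle_decay = FALSE)
  expect_lt(cod_report(good, p)$drift, 1e-5)
  expect_gt(cod_report(broken, p)$drift, 1e-3)
  # trapezoid fallback when the integral column is absent (finely sampled,
  # since the reconstruction is only quadrature-accurate)
  fine <- rk4_oracle(p, s0, t_end = 5, h = 1e-3, report_every = 0.01)
  no_col <- fine[, setdiff(names(fine), "growth_cod")]
  expect_lt(cod_report(no_col, p)$drift, 1e-4)
  # zero trajectory has zero drift
  z <- simulate_ad(p, model_state(), t_end = 2, report_step = 1)
  expect_equal(cod_report(z)$drift, 0)
})

test_that("integration rejects invalid horizons and writes the documented
           trajectory columns", {
  p <- ad_params()
  expect_error(simulate_ad(p, model_state(), t_end = -1), "positive")
  expect_error(simulate_ad(p, model_state(), times = c(1, 2)), "start at 0")
  s0 <- initial_state(substrate_ns1(), inoculum_spec(), batch_config())
  traj <- simulate_ad(p, s0, t_end = 2, report_step = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(traj, path)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(hdr, c("time_d", "S_p", "S_h", "S_v", "S_fa", "S_m",
                          "X_h", "X_v", "X_m", "S_Ca", "K_h", "K_v", "K_m"))
})
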