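# Independent oracles: a fixed-step RK4 integrator with its own coding of the
# model equations (used to cross-check the adaptive compiled path), plus small
# brute-force helpers.

# Right-hand side written independently from the package implementation.
# y = c(S_p, S_h, S_v, S_fa, S_m, X_h, X_v, X_m, S_Ca, growth_cod).
# recycle_decay = FALSE gives a deliberately broken variant (decayed biomass
# COD vanishes) for negative-control tests of the balance report.
oracle_rhs <- function(y, p, recycle_decay = TRUE) {
  S_p <- y[1]; S_h <- y[2]; S_v <- y[3]; S_fa <- y[4]
  X_h <- y[6]; X_v <- y[7]; X_m <- y[8]; S_Ca <- y[9]
  pool <- p$a * (X_h + X_v + X_m) + p$b * S_Ca
  K <- function(Kifa) if (S_fa > 0) Kifa * pool / (Kifa * pool + S_fa^2) else 1
  uptake <- function(km, Ks, S, X) {
    den <- Ks * X + S
    if (S > 0 && X > 0 && den > 0) km * S / den * X else 0
  }
  r_p <- uptake(p$km_p, p$Ks_p, S_p, X_h) * K(p$Khfa)
  r_h <- uptake(p$km_h, p$Ks_h, S_h, X_v) * K(p$Kvfa)
  r_v <- uptake(p$km_v, p$Ks_v, S_v, X_m) * K(p$Kmfa)
  r_fa <- uptake(p$km_fa, p$Ks_fa, S_fa, X_v) * K(p$Kvfa)
  decay <- if (recycle_decay)
    p$kd_h * X_h + p$kd_v * X_v + p$kd_m * X_m else 0
  c(-r_p + decay,
    r_p - r_h,
    r_h - r_v,
    p$f_fa * r_p - r_fa,
    r_v,
    p$Y_h * r_p - p$kd_h * X_h,
    p$Y_v * r_h - p$kd_v * X_v,
    p$Y_m * r_v - p$kd_m * X_m,
    0,
    p$Y_h * r_p + p$Y_v * r_h + p$Y_m * r_v)
}

# Classical RK4 with fixed step h; reports at whole multiples of report_every
# (days). Returns a data frame shaped like an ad_trajectory (states plus
# growth_cod), without inhibition columns.
rk4_oracle <- function(params, state0, t_end, h, report_every = 1,
                       recycle_decay = TRUE) {
  p <- as.list(params)
  y <- c(unname(state0[c("S_p", "S_h", "S_v", "S_fa", "S_m",
                         "X_h", "X_v", "X_m", "S_Ca")]), 0)
  n <- round(t_end / h)
  every <- round(report_every / h)
  out <- matrix(NA_real_, floor(n / every) + 1L, 11L)
  out[1L, ] <- c(0, y)
  row <- 2L
  for (i in seq_len(n)) {
    k1 <- oracle_rhs(y, p, recycle_decay)
    k2 <- oracle_rhs(y + h / 2 * k1, p, recycle_decay)
    k3 <- oracle_rhs(y + h / 2 * k2, p, recycle_decay)
    k4 <- oracle_rhs(y + h * k3, p, recycle_decay)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    y <- pmax(y, 0)
    if (i %% every == 0L) {
      out[row, ] <- c(i * h, y)
      row <- row + 1L
    }
  }
  df <- as.data.frame(out)
  names(df) <- c("time_d", "S_p", "S_h", "S_v", "S_fa", "S_m",
                 "X_h", "X_v", "X_m", "S_Ca", "growth_cod")
  df
}

# Brute-force sum of squared differences between simulated and observed
# cumulative methane, written as explicit loops.
loop_ssq <- function(params, datasets) {
  total <- 0
  for (ds in datasets) {
    p <- params
    p$f_fa <- ds$substrate$f_fa
    s0 <- initial_state(ds$substrate, ds$inoculum, ds$config)
    times <- sort(unique(c(0, ds$curve$day)))
    traj <- simulate_ad(p, s0, times = times)
    for (j in seq_len(nrow(ds$curve))) {
      sim <- traj$S_m[which(times == ds$curve$day[j])] *
        ds$conversions$ch4_per_cod
      total <- total + (sim - ds$curve$cumulative_CH4_L_per_L[j])^2
    }
  }
  total
}
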