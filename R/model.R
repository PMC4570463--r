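# ODE right-hand side, trajectory integration and COD accounting.

# Full 10-component RHS (9 pools + cumulative biomass-synthesis COD) on a
# clamped state; `pv` is the ordered parameter vector. Mirrors src/adlcfa.c.
.rhs_full <- function(y, pv) {
  y <- pmax(y, 0)
  S_p <- y[1]; S_h <- y[2]; S_v <- y[3]; S_fa <- y[4]
  X_h <- y[6]; X_v <- y[7]; X_m <- y[8]; S_Ca <- y[9]

  C <- pv[19] * (X_h + X_v + X_m) + pv[20] * S_Ca
  K_h <- .inhib(pv[16], C, S_fa)
  K_v <- .inhib(pv[17], C, S_fa)
  K_m <- .inhib(pv[18], C, S_fa)

  ctois <- function(km, Ks, S, X, K) {
    den <- Ks * X + S
    if (S <= 0 || X <= 0 || den <= 0) 0 else km * S / den * X * K
  }
  r_p  <- ctois(pv[1], pv[5], S_p,  X_h, K_h)
  r_h  <- ctois(pv[2], pv[6], S_h,  X_v, K_v)
  r_v  <- ctois(pv[4], pv[8], S_v,  X_m, K_m)
  r_fa <- ctois(pv[3], pv[7], S_fa, X_v, K_v)

  c(-r_p + pv[12] * X_h + pv[13] * X_v + pv[14] * X_m,
    r_p - r_h,
    r_h - r_v,
    pv[15] * r_p - r_fa,
    r_v,
    pv[9] * r_p - pv[12] * X_h,
    pv[10] * r_h - pv[13] * X_v,
    pv[11] * r_v - pv[14] * X_m,
    0,
    pv[9] * r_p + pv[10] * r_h + pv[11] * r_v)
}

#' Model right-hand side
#'
#' Time derivative of the nine pools (kg COD/m^3/day). Hydrolysis,
#' acidogenesis and methanogenesis follow Contois kinetics, each multiplied
#' by its group's LCFA inhibition factor; biomass decays at first order and
#' the decayed COD is recycled into the particulate pool; the LCFA pool is
#' fed by the fraction `f_fa` of the hydrolysis flux and consumed by the
#' acidogens; the calcium equivalent is constant.
#'
#' @param params An [ad_params()] object.
#' @param state A [model_state()] vector.
#' @return Named numeric vector of derivatives, one per state.
#' @examples
#' p <- ad_params()
#' ad_rhs(p, model_state(S_p = 28.3, X_h = 1))
#' @export
ad_rhs <- function(params, state) {
  validate_params(params)
  state <- do.call(model_state, as.list(state[.state_order]))
  d <- .rhs_full(c(state, 0), as_param_vector(params))
  setNames(d[1:9], .state_order)
}

#' Integrate the digestion model
#'
#' Adaptive stiff-capable integration (deSolve, `lsoda` by default) of the
#' model from an initial state. By default the compiled C right-hand side is
#' used; `compiled = FALSE` switches to the R implementation (identical
#' algebra, used for cross-checks). Reported states are clipped to zero when
#' they undershoot by less than `clip_tol`; a larger negative value is an
#' integration error. The cumulative methane pool is checked to be
#' non-decreasing.
#'
#' @param params An [ad_params()] object.
#' @param state0 Initial [model_state()].
#' @param t_end Horizon, days.
#' @param report_step Reporting interval, days.
#' @param times Optional explicit reporting times (days, starting at 0);
#'   overrides `t_end`/`report_step`.
#' @param method deSolve integration method.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param compiled Use the compiled RHS (default) or the R RHS.
#' @param clip_tol Negative undershoot tolerated and clipped to 0.
#' @return An `ad_trajectory`: data frame with columns `time_d`, the nine
#'   states, the inhibition factors `K_h`, `K_v`, `K_m` and the auxiliary
#'   `growth_cod` integral; attributes `params` and `diagnostics`.
#' @export
simulate_ad <- function(params, state0, t_end = 20, report_step = 0.25,
                        times = NULL, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10,
                        compiled = TRUE, clip_tol = 1e-10) {
  validate_params(params)
  state0 <- do.call(model_state, as.list(state0[.state_order]))
  if (is.null(times)) {
    if (t_end <= 0 || report_step <= 0)
      stop("t_end and report_step must be positive")
    times <- seq(0, t_end, by = report_step)
    if (utils::tail(times, 1) < t_end) times <- c(times, t_end)
  } else {
    if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
      stop("times must start at 0 and be strictly increasing")
  }
  pv <- as_param_vector(params)
  y0 <- c(state0, growth_cod = 0)

  out <- if (compiled) {
    deSolve::ode(y = y0, times = times, func = "adlcfa_derivs", parms = pv,
                 dllname = "adlcfa", initfunc = "adlcfa_init",
                 method = method, rtol = rtol, atol = atol)
  } else {
    deSolve::ode(y = y0, times = times,
                 func = function(t, y, p) list(.rhs_full(y, p)), parms = pv,
                 method = method, rtol = rtol, atol = atol)
  }
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop("integration failed (istate = ", istate[1], ")")
  m <- unclass(out)
  if (nrow(m) < length(times))
    stop("integration stopped early at t = ", max(m[, 1]))

  states <- m[, -1, drop = FALSE]
  if (any(states < -clip_tol))
    stop("integration produced negative states beyond tolerance (min = ",
         format(min(states)), ")")
  states[states < 0] <- 0

  S_m <- states[, "S_m"]
  if (any(diff(S_m) < -1e-8 * max(S_m, 1)))
    stop("cumulative methane decreased along the trajectory")

  C <- pv[19] * rowSums(states[, c("X_h", "X_v", "X_m"), drop = FALSE]) +
    pv[20] * states[, "S_Ca"]
  traj <- data.frame(time_d = m[, 1], states,
                     K_h = .inhib(pv[16], C, states[, "S_fa"]),
                     K_v = .inhib(pv[17], C, states[, "S_fa"]),
                     K_m = .inhib(pv[18], C, states[, "S_fa"]))
  attr(traj, "params") <- params
  attr(traj, "diagnostics") <- list(method = method, rtol = rtol, atol = atol,
                                    compiled = compiled,
                                    n_steps = if (!is.null(istate)) istate[3]
                                              else NA_integer_)
  class(traj) <- c("ad_trajectory", "data.frame")
  traj
}

#' COD balance report for a trajectory
#'
#' The model's product pools receive the full uptake flux while biomass is
#' synthesised in addition at yield `Y`, so the checkable conserved quantity
#' is the pool sum `S_p + S_h + S_v + S_m + X_h + X_v + X_m` minus the
#' integrated biomass-synthesis source (`growth_cod`). The LCFA pool `S_fa`
#' is a tracking pool (its inflow duplicates part of the hydrolysate flux)
#' and is reported separately, outside the balance. If the trajectory carries
#' the solver-integrated `growth_cod` column it is used; otherwise the source
#' term is reconstructed by trapezoidal quadrature of the states.
#'
#' @param trajectory An `ad_trajectory` (or data frame with the same state
#'   columns).
#' @param params Parameter set; defaults to the trajectory's own.
#' @return List of class `cod_report` with elements `drift` (maximum
#'   relative deviation of the balance from its initial value) and `table`
#'   (per-time-point balance and `S_fa`).
#' @export
cod_report <- function(trajectory, params = attr(trajectory, "params")) {
  validate_params(params)
  need <- c("time_d", "S_p", "S_h", "S_v", "S_m", "X_h", "X_v", "X_m")
  if (!all(need %in% names(trajectory)))
    stop("trajectory lacks required columns")
  pools <- rowSums(trajectory[, c("S_p", "S_h", "S_v", "S_m",
                                  "X_h", "X_v", "X_m")])
  growth <- if ("growth_cod" %in% names(trajectory)) {
    trajectory$growth_cod
  } else {
    pv <- as_param_vector(params)
    src <- apply(as.matrix(trajectory[, c(.state_order)]), 1, function(s) {
      d <- .rhs_full(c(s, 0), pv)
      d[10]
    })
    t <- trajectory$time_d
    c(0, cumsum(diff(t) * (utils::head(src, -1) + utils::tail(src, -1)) / 2))
  }
  balance <- pools - growth
  ref <- balance[1]
  drift <- if (ref > 0) max(abs(balance - ref)) / ref else max(abs(balance - ref))
  out <- list(drift = drift,
              table = data.frame(time_d = trajectory$time_d,
                                 cod_balance = balance,
                                 growth_cod = growth,
                                 S_fa = trajectory$S_fa))
  class(out) <- "cod_report"
  out
}

#' @export
print.cod_report <- function(x, ...) {
  cat("COD balance report:", nrow(x$table), "time points\n")
  cat("  initial balance :", format(x$table$cod_balance[1]), "kg COD/m3\n")
  cat("  max rel. drift  :", format(x$drift), "\n")
  invisible(x)
}

#' Write a trajectory as delimited text
#'
#' Tab-separated columns `time_d, S_p, S_h, S_v, S_fa, S_m, X_h, X_v, X_m,
#' S_Ca, K_h, K_v, K_m`.
#'
#' @param trajectory An `ad_trajectory`.
#' @param path Output path.
#' @export
write_trajectory <- function(trajectory, path) {
  cols <- c("time_d", "S_p", "S_h", "S_v", "S_fa", "S_m",
            "X_h", "X_v", "X_m", "S_Ca", "K_h", "K_v", "K_m")
  write.table(trajectory[, cols], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
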