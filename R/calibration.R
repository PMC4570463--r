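# Calibration of the estimated parameters against cumulative methane curves
# by bound-constrained Levenberg-Marquardt least squares.

#' Bundle one batch configuration with its observed methane curve
#'
#' @param config A [batch_config()].
#' @param curve A `methane_curve` (columns `day`,
#'   `cumulative_CH4_L_per_L`).
#' @param substrate A [substrate_spec()] (supplies `f_fa` and COD density).
#' @param inoculum An [inoculum_spec()].
#' @param conversions A [unit_conversions()].
#' @return List of class `bmp_dataset`.
#' @export
bmp_dataset <- function(config, curve, substrate,
                        inoculum = inoculum_spec(),
                        conversions = unit_conversions()) {
  if (!all(c("day", "cumulative_CH4_L_per_L") %in% names(curve)))
    stop("curve must have columns day and cumulative_CH4_L_per_L")
  structure(list(config = config, curve = curve, substrate = substrate,
                 inoculum = inoculum, conversions = conversions),
            class = "bmp_dataset")
}

# Simulated cumulative methane volume at the dataset's observation days.
.predict_curve <- function(params, ds, rtol = 1e-8, atol = 1e-10) {
  params$f_fa <- ds$substrate$f_fa
  s0 <- initial_state(ds$substrate, ds$inoculum, ds$config)
  days <- ds$curve$day
  times <- sort(unique(c(0, days)))
  traj <- simulate_ad(params, s0, times = times, rtol = rtol, atol = atol)
  traj$S_m[match(days, times)] * ds$conversions$ch4_per_cod
}

# Residual vector over all datasets and days. Three residual forms:
#  - cumulative: simulated - observed cumulative volume (unweighted);
#  - cumulative_scaled: the same, divided by each curve's maximum observed
#    value (per-curve normalization, equalizing curves of unequal size);
#  - relative_increment: daily increments differenced and divided by the
#    simulated increment — the whitened residual when measurement noise is
#    multiplicative on daily increments, as in generate_bmp_study(). The
#    divisor is floored at 1e-3 of the curve's largest simulated increment
#    and residuals are capped at 1e4 to keep the optimizer finite.
.fit_residuals <- function(free, datasets, fixed,
                           loss = "cumulative",
                           on_error = c("penalty", "error")) {
  on_error <- match.arg(on_error)
  params <- modifyList(fixed, as.list(free))
  class(params) <- "ad_params"
  unlist(lapply(datasets, function(ds) {
    obs <- ds$curve$cumulative_CH4_L_per_L
    tryCatch({
      pred <- .predict_curve(params, ds)
      switch(loss,
        cumulative = pred - obs,
        cumulative_scaled = (pred - obs) / max(obs, 1e-9),
        relative_increment = {
          pi <- diff(pred)
          r <- (pi - diff(obs)) / pmax(pi, 1e-3 * max(pi, 1e-9))
          pmin(pmax(r, -1e4), 1e4)
        },
        stop("unknown loss: ", loss))
    }, error = function(e) {
      if (on_error == "error" || !grepl("integration|negative states|methane",
                                        conditionMessage(e)))
        stop(e)
      warning("simulation failed during fit (", conditionMessage(e),
              "); penalty residuals used", call. = FALSE)
      rep(1e3, if (loss == "relative_increment") length(obs) - 1
          else length(obs))
    })
  }), use.names = FALSE)
}

#' Sum-of-squares calibration objective
#'
#' Sum over datasets and observation days of the squared difference between
#' simulated and observed cumulative methane volume (units (L CH4/L)^2).
#' The simulation is sampled exactly at the observation days.
#'
#' @param free Named numeric vector of free-parameter values (names drawn
#'   from [estimated_parameters()] or any model parameter).
#' @param datasets List of [bmp_dataset()] objects.
#' @param fixed An [ad_params()] set supplying all non-free parameters
#'   (each dataset's `f_fa` is taken from its substrate).
#' @param on_error `"penalty"` (default) replaces residuals of a failed
#'   simulation by a large constant with a warning; `"error"` propagates.
#' @return Scalar sum of squared residuals.
#' @export
objective_ssq <- function(free, datasets, fixed = ad_params(),
                          on_error = c("penalty", "error")) {
  if (!length(datasets)) stop("at least one dataset is required")
  sum(.fit_residuals(free, datasets, fixed, "cumulative", on_error)^2)
}

# Default box bounds: (0.1x, 10x) the reference values, with the inhibition
# weights additionally confined to [0, 1].
.default_bounds <- function(fixed, free_names) {
  ref <- vapply(fixed[free_names], as.numeric, numeric(1))
  lower <- 0.1 * ref
  upper <- 10 * ref
  for (w in intersect(c("a", "b"), free_names)) {
    lower[w] <- max(lower[w], 0)
    upper[w] <- min(upper[w], 1)
  }
  list(lower = lower, upper = upper)
}

#' Fit model parameters to methane curves
#'
#' Bound-constrained Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm()]) on the concatenated residuals of all datasets.
#' Deterministic given `init` (and `multi_start_seeds`, if used).
#'
#' The inhibition weights and constants are jointly identified only up to a
#' common scale (multiplying `a`, `b` by a constant and dividing `Khfa`,
#' `Kvfa`, `Kmfa` by the same constant leaves every trajectory unchanged),
#' so when both `a` and `b` are free the default `normalize_weights = TRUE`
#' fixes the gauge `a + b = 1`: the fit runs over `a` with `b = 1 - a`, and
#' both are reported. Set `normalize_weights = FALSE` for the raw
#' (degenerate) parameterization.
#'
#' @param datasets List of [bmp_dataset()] objects (at least one).
#' @param free_names Parameters to estimate; default [estimated_parameters()].
#' @param fixed An [ad_params()] set holding the remaining parameters.
#' @param init Named starting values; default the values in `fixed`. Must lie
#'   within the bounds.
#' @param lower,upper Named bounds; default 0.1x / 10x the `fixed` values,
#'   with `a`, `b` confined to \[0, 1\].
#' @param normalize_weights Impose the `a + b = 1` gauge (default TRUE when
#'   both weights are free).
#' @param loss Residual form: `"cumulative"` (default; unweighted residuals
#'   on the cumulative curves), `"cumulative_scaled"` (per-curve max
#'   normalization) or `"relative_increment"` (daily increments divided by
#'   the simulated increment — the whitened likelihood when noise is
#'   multiplicative on daily increments, as in [generate_bmp_study()];
#'   recommended for such data).
#' @param multi_start_seeds Optional integer vector; one additional start per
#'   seed, drawn by jittering `init` within +/-20% (clipped to bounds); the
#'   best final objective wins.
#' @param control A [minpack.lm::nls.lm.control()] list. The default uses a
#'   forward-difference step of about 1e-3 relative (`epsfcn = 1e-6`): the
#'   residuals are ODE solutions with error near the solver tolerance, so the
#'   machine-precision default step would difference solver noise in
#'   weakly-identified directions.
#' @param on_error Simulation-failure policy, see [objective_ssq()].
#' @return List of class `fit_result`: `estimates` (all free parameters,
#'   including the reconstructed `b` under the gauge), `objective`,
#'   `residuals`, `converged`, `info`, `message`, `niter`, `bounds`, `init`.
#' @export
fit_params <- function(datasets, free_names = estimated_parameters(),
                       fixed = ad_params(), init = NULL,
                       lower = NULL, upper = NULL,
                       normalize_weights = all(c("a", "b") %in% free_names),
                       loss = c("cumulative", "cumulative_scaled",
                                "relative_increment"),
                       multi_start_seeds = NULL,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, maxfev = 5000,
                         ftol = 1e-14, ptol = 1e-14, epsfcn = 1e-6),
                       on_error = c("penalty", "error")) {
  if (!length(datasets)) stop("at least one dataset is required")
  loss <- match.arg(loss)
  validate_params(fixed)
  stopifnot(all(free_names %in% .param_order))

  b <- .default_bounds(fixed, free_names)
  if (is.null(lower)) lower <- b$lower else lower <- lower[free_names]
  if (is.null(upper)) upper <- b$upper else upper <- upper[free_names]
  if (is.null(init)) init <- vapply(fixed[free_names], as.numeric, numeric(1))
  init <- init[free_names]
  if (any(init < lower - 1e-12) || any(init > upper + 1e-12))
    stop("init must lie within the bounds")

  gauge <- normalize_weights && all(c("a", "b") %in% free_names)
  if (gauge) {
    int_names <- setdiff(free_names, "b")
    to_full <- function(th) {
      full <- th
      full["b"] <- 1 - th[["a"]]
      full[free_names]
    }
    init_int <- init[int_names]
    init_int["a"] <- init[["a"]] / (init[["a"]] + init[["b"]])
    lower_int <- lower[int_names]
    upper_int <- upper[int_names]
    lower_int["a"] <- max(lower[["a"]], 1 - upper[["b"]])
    upper_int["a"] <- min(upper[["a"]], 1 - lower[["b"]])
    init_int["a"] <- min(max(init_int[["a"]], lower_int[["a"]]),
                         upper_int[["a"]])
  } else {
    int_names <- free_names
    to_full <- identity
    init_int <- init
    lower_int <- lower
    upper_int <- upper
  }

  resid_fn <- function(th) {
    names(th) <- int_names
    .fit_residuals(to_full(th), datasets, fixed, loss, on_error)
  }

  starts <- list(init_int)
  for (seed in multi_start_seeds) {
    set.seed(seed)
    jit <- init_int * runif(length(init_int), 0.8, 1.2)
    starts[[length(starts) + 1L]] <- pmin(pmax(jit, lower_int), upper_int)
  }

  runs <- lapply(starts, function(st)
    minpack.lm::nls.lm(par = st, lower = lower_int, upper = upper_int,
                       fn = resid_fn, control = control))
  best <- runs[[which.min(vapply(runs, function(r) r$deviance, numeric(1)))]]

  est <- to_full(setNames(as.numeric(best$par), int_names))
  out <- list(estimates = est,
              objective = best$deviance,
              objective_init = sum(resid_fn(init_int)^2),
              loss = loss,
              residuals = as.numeric(best$fvec),
              converged = best$info %in% 1:4,
              info = best$info,
              message = best$message,
              niter = best$niter,
              bounds = list(lower = lower, upper = upper),
              init = init,
              gauge = if (gauge) "a+b=1" else "none",
              n_starts = length(starts))
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Calibration fit (", if (x$converged) "converged" else "NOT converged",
      ", ", x$niter, " iterations, gauge: ", x$gauge,
      ", loss: ", x$loss, ")\n", sep = "")
  cat("  objective (SSQ):", format(x$objective), "\n")
  print(round(x$estimates, 5))
  invisible(x)
}

#' Write a fit result as a JSON report
#'
#' @param fit A `fit_result`.
#' @param path Output path.
#' @export
write_fit_report <- function(fit, path) {
  jsonlite::write_json(
    list(estimates = as.list(fit$estimates),
         objective = fit$objective,
         objective_init = fit$objective_init,
         loss = fit$loss,
         converged = fit$converged,
         info = fit$info,
         message = fit$message,
         niter = fit$niter,
         gauge = fit$gauge,
         bounds = lapply(fit$bounds, as.list),
         init = as.list(fit$init)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
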