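# Local relative sensitivity: (relative change in output) / (relative change
# in parameter), used to partition parameters into fixed and estimated sets.

#' Bundle a simulation scenario
#'
#' @param substrate A [substrate_spec()].
#' @param inoculum An [inoculum_spec()].
#' @param config A [batch_config()].
#' @param conversions A [unit_conversions()].
#' @return List of class `ad_scenario`.
#' @export
ad_scenario <- function(substrate = substrate_ns1(),
                        inoculum = inoculum_spec(),
                        config = batch_config(),
                        conversions = unit_conversions()) {
  structure(list(substrate = substrate, inoculum = inoculum, config = config,
                 conversions = conversions), class = "ad_scenario")
}

# Output functionals for a scenario. The parameters are used exactly as
# passed (in particular f_fa, so that its own sensitivity is measurable):
# build base_params with the substrate's f_fa. "curve" returns the daily
# cumulative methane volumes; "final" its last value.
.scenario_output_fn <- function(scenario, functional = c("curve", "final")) {
  functional <- match.arg(functional)
  force(scenario)
  function(params) {
    s0 <- initial_state(scenario$substrate, scenario$inoculum,
                        scenario$config)
    traj <- simulate_ad(params, s0, t_end = scenario$config$duration,
                        report_step = 1)
    y <- traj$S_m * scenario$conversions$ch4_per_cod
    if (functional == "final") y[length(y)] else y
  }
}

#' Relative sensitivity of a model output to one parameter
#'
#' Computes `delta = (dy/y) / (dp/p)`, the relative change in the output per
#' relative change in the parameter, by a central difference at
#' `+/- perturbation` (or a one-sided upper difference with
#' `side = "upper"`, which permits a full +100% perturbation). The default
#' output is the scenario's daily cumulative methane curve
#' (`functional = "curve"`): `delta` is computed day by day and the value of
#' largest magnitude is returned, so a parameter that only shifts the lag
#' phase registers even though the final volume is unchanged.
#' `functional = "final"` uses the end-of-batch volume only. `reciprocal =
#' TRUE` returns `1/delta` (the printed orientation of the sensitivity
#' function in part of the literature).
#'
#' If the perturbed outputs equal the baseline everywhere the parameter has
#' no local influence and `delta = 0`, even at a zero baseline; a zero
#' baseline with a nonzero response is an error (the relative change is
#' undefined). Days with baseline volume below `y_floor` are excluded from
#' the day-wise ratio.
#'
#' @param param_name One of the model parameter names.
#' @param base_params An [ad_params()] set. When using the default scenario
#'   functional, its `f_fa` should be the scenario substrate's.
#' @param scenario An [ad_scenario()]; ignored when `output_fn` is given.
#' @param perturbation Relative perturbation in (0, 1\].
#' @param output_fn Optional function `params -> output` returning a scalar
#'   or a vector (day-wise aggregation as above).
#' @param functional Default scenario output: `"curve"` or `"final"`.
#' @param side `"central"` (default) or `"upper"`.
#' @param reciprocal Return `1/delta`.
#' @param y_floor Baseline values at or below this are excluded, L CH4/L.
#' @return Scalar `delta` (dimensionless).
#' @export
relative_sensitivity <- function(param_name, base_params,
                                 scenario = ad_scenario(),
                                 perturbation = 0.5,
                                 output_fn = NULL,
                                 functional = c("curve", "final"),
                                 side = c("central", "upper"),
                                 reciprocal = FALSE,
                                 y_floor = 1e-6) {
  side <- match.arg(side)
  if (perturbation <= 0 || perturbation > 1)
    stop("perturbation must lie in (0, 1]")
  p0 <- as.numeric(base_params[[param_name]])
  if (!length(p0) || !is.finite(p0) || p0 <= 0)
    stop("base parameter must be strictly positive")
  if (side == "central" && perturbation >= 1)
    stop("a central difference at +/-100% would zero the parameter; ",
         "use side = \"upper\"")
  if (is.null(output_fn))
    output_fn <- .scenario_output_fn(scenario, match.arg(functional))

  eval_at <- function(val) {
    p <- base_params
    p[[param_name]] <- val
    output_fn(p)
  }
  y0 <- output_fn(base_params)
  y_up <- eval_at(p0 * (1 + perturbation))
  if (side == "central") {
    y_dn <- eval_at(p0 * (1 - perturbation))
    dy <- y_up - y_dn
    dp_rel <- 2 * perturbation
  } else {
    dy <- y_up - y0
    dp_rel <- perturbation
  }
  if (all(dy == 0))
    return(if (reciprocal) stop("delta is 0; reciprocal undefined") else 0)
  keep <- y0 > y_floor
  if (!any(keep))
    stop("output is zero at the baseline; relative sensitivity undefined")
  d <- (dy[keep] / y0[keep]) / dp_rel
  delta <- d[which.max(abs(d))]
  if (reciprocal) 1 / delta else delta
}

# Default screening scenarios: the full experimental grid for the high-lipid
# substrate, so that each mechanism (inhibition, calcium, decay) is active
# somewhere in the set.
.default_screen_scenarios <- function() {
  grid <- expand.grid(is_ratio = c(0.1, 0.4, 1.0),
                      ca_ratio = c(0, 0.5, 1, 2), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    ad_scenario(config = batch_config(is_ratio = grid$is_ratio[i],
                                      ca_ratio = grid$ca_ratio[i])))
}

#' Sensitivity screen over the model parameters
#'
#' Evaluates [relative_sensitivity()] for each parameter across a set of
#' scenarios (default: the 3 I/S x 4 calcium experimental grid of the
#' high-lipid substrate) and classifies each by the maximum magnitude:
#' `|delta| > threshold` is "high" (to be estimated), otherwise "low" (kept
#' at literature values). A parameter is retained if it is influential
#' anywhere in the design space.
#'
#' @param base_params An [ad_params()] set.
#' @param param_names Parameters to screen (default: all 20).
#' @param scenarios List of [ad_scenario()]s.
#' @param threshold Classification threshold on `|delta|` (> 0 high).
#' @param perturbation Relative perturbation, see [relative_sensitivity()].
#' @param side Difference scheme, see [relative_sensitivity()].
#' @return Data frame `parameter, delta, class`, sorted by decreasing
#'   `|delta|`; attributes `threshold`, `perturbation`.
#' @export
sensitivity_screen <- function(base_params = ad_params(),
                               param_names = .param_order,
                               scenarios = .default_screen_scenarios(),
                               threshold = 0.1, perturbation = 0.5,
                               side = c("central", "upper")) {
  side <- match.arg(side)
  if (threshold < 0) stop("threshold must be non-negative")
  stopifnot(all(param_names %in% .param_order), length(scenarios) >= 1)
  delta <- vapply(param_names, function(nm) {
    d <- vapply(scenarios, function(sc)
      relative_sensitivity(nm, base_params, scenario = sc,
                           perturbation = perturbation, side = side),
      numeric(1))
    d[which.max(abs(d))]
  }, numeric(1))
  out <- data.frame(parameter = param_names,
                    delta = as.numeric(delta),
                    class = ifelse(abs(delta) > threshold, "high", "low"),
                    row.names = NULL)
  out <- out[order(-abs(out$delta)), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "perturbation") <- perturbation
  out
}
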