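# Kinetic/stoichiometric parameter set and its flat-file representation.

.param_order <- c("km_p", "km_h", "km_fa", "km_v",
                  "Ks_p", "Ks_h", "Ks_fa", "Ks_v",
                  "Y_h", "Y_v", "Y_m",
                  "kd_h", "kd_v", "kd_m",
                  "f_fa",
                  "Khfa", "Kvfa", "Kmfa",
                  "a", "b")

#' Kinetic and stoichiometric model parameters
#'
#' Constructs the full parameter set of the digestion model. Defaults are the
#' literature/initial values used for *Nannochloropsis salina* whole biomass
#' (NS1); the only substrate-specific default is `f_fa`, the fatty-acid
#' fraction of hydrolysis products (0.35 for whole biomass, 0.11 for
#' lipid-extracted residue).
#'
#' @param km_p,km_h,km_fa,km_v Maximum specific uptake rates for particulate
#'   hydrolysis, hydrolysate acidogenesis, LCFA uptake and VFA methanogenesis
#'   (1/day).
#' @param Ks_p,Ks_h,Ks_fa,Ks_v Contois half-saturation coefficients
#'   (dimensionless, COD/COD).
#' @param Y_h,Y_v,Y_m Biomass yields of the three groups (kg COD/kg COD),
#'   each in (0, 1).
#' @param kd_h,kd_v,kd_m First-order decay rates (1/day).
#' @param f_fa Fatty-acid fraction of the hydrolysis flux (dimensionless,
#'   in \[0, 1\]).
#' @param Khfa,Kvfa,Kmfa LCFA inhibition constants for hydrolytic bacteria,
#'   acidogens and methanogens (kg COD/m^3).
#' @param a,b Dimensionless weights on active biomass and on the calcium
#'   binding equivalent in the inhibition ratio.
#' @return A named list of class `ad_params`.
#' @examples
#' p <- ad_params()               # NS1 defaults
#' p2 <- ad_params(f_fa = 0.11)   # lipid-extracted residue
#' @export
ad_params <- function(km_p = 10, km_h = 20, km_fa = 6, km_v = 20,
                      Ks_p = 0.5, Ks_h = 0.5, Ks_fa = 0.5, Ks_v = 0.5,
                      Y_h = 0.05, Y_v = 0.05, Y_m = 0.05,
                      kd_h = 0.8, kd_v = 0.8, kd_m = 0.05,
                      f_fa = 0.35,
                      Khfa = 5, Kvfa = 5, Kmfa = 5,
                      a = 0.5, b = 0.5) {
  p <- mget(.param_order)
  p <- lapply(p, as.numeric)
  class(p) <- "ad_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity of all rates and constants, yields in (0, 1) and
#' `f_fa` in \[0, 1\].
#'
#' @param p An `ad_params` object or named list covering all parameters.
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(p) {
  missing <- setdiff(.param_order, names(p))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  v <- vapply(p[.param_order], function(x) as.numeric(x)[1], numeric(1))
  if (any(!is.finite(v)))
    stop("non-finite parameter value(s): ",
         paste(.param_order[!is.finite(v)], collapse = ", "))
  if (any(v <= 0 & .param_order != "f_fa"))
    stop("parameters must be strictly positive: ",
         paste(.param_order[v <= 0 & .param_order != "f_fa"], collapse = ", "))
  yields <- v[c("Y_h", "Y_v", "Y_m")]
  if (any(yields <= 0 | yields >= 1))
    stop("yields Y_h, Y_v, Y_m must lie in (0, 1)")
  if (v["f_fa"] < 0 || v["f_fa"] > 1)
    stop("f_fa must lie in [0, 1]")
  invisible(p)
}

# Ordered numeric vector handed to the compiled RHS.
as_param_vector <- function(p) {
  vapply(p[.param_order], function(x) as.numeric(x)[1], numeric(1))
}

#' Names of the calibrated parameters
#'
#' The eight parameters estimated from batch methane curves (the remaining
#' twelve are taken from literature values): the methanogenesis rate and
#' stoichiometry (`km_v`, `Y_m`, `kd_m`), the three group-specific LCFA
#' inhibition constants (`Khfa`, `Kvfa`, `Kmfa`) and the inhibition-ratio
#' weights (`a`, `b`).
#'
#' @return Character vector of length 8.
#' @export
estimated_parameters <- function() {
  c("km_v", "Y_m", "kd_m", "Khfa", "Kvfa", "Kmfa", "a", "b")
}

#' Read / write a parameter file
#'
#' Parameters are stored as a flat YAML map whose keys are exactly the
#' parameter names (`km_p`, `Ks_p`, ..., `Khfa`, `f_fa`, `a`, `b`).
#'
#' @param path File path.
#' @return `read_params()` returns an `ad_params` object.
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(ad_params, x[intersect(names(x), .param_order)])
}

#' @rdname read_params
#' @param p An `ad_params` object.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  yaml::write_yaml(lapply(p[.param_order], as.numeric), path)
  invisible(path)
}

#' @export
print.ad_params <- function(x, ...) {
  cat("Anaerobic digestion model parameters\n")
  v <- as_param_vector(x)
  print(v)
  invisible(x)
}
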