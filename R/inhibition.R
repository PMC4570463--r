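# LCFA inhibition factors: non-competitive multipliers on each functional
# group, driven by the (biomass + calcium equivalent):LCFA ratio.

.state_order <- c("S_p", "S_h", "S_v", "S_fa", "S_m",
                  "X_h", "X_v", "X_m", "S_Ca")

#' Model state vector
#'
#' The nine concentration pools of the model, all in kg COD/m^3 (equivalently
#' g COD/L): particulate substrate `S_p`, soluble hydrolysate `S_h`, VFA
#' `S_v`, LCFA `S_fa`, cumulative methane `S_m`, the three biomass groups
#' `X_h`/`X_v`/`X_m`, and the calcium LCFA-binding equivalent `S_Ca`
#' (constant along a trajectory).
#'
#' @param S_p,S_h,S_v,S_fa,S_m,X_h,X_v,X_m,S_Ca Non-negative concentrations,
#'   kg COD/m^3.
#' @return Named numeric vector of length 9.
#' @export
model_state <- function(S_p = 0, S_h = 0, S_v = 0, S_fa = 0, S_m = 0,
                        X_h = 0, X_v = 0, X_m = 0, S_Ca = 0) {
  s <- vapply(mget(.state_order), function(x) as.numeric(x)[1], numeric(1))
  if (any(!is.finite(s)) || any(s < 0))
    stop("model state must be finite and non-negative")
  s
}

# Core algebra, no validation; vectorized over states.
.inhib <- function(K_ifa, C, S_fa) {
  ifelse(S_fa <= 0, 1, K_ifa * C / (K_ifa * C + S_fa^2))
}

#' Non-competitive LCFA inhibition factor
#'
#' Dimensionless multiplier in \[0, 1\] applied to an uptake rate. The factor
#' saturates in the ratio `R = (a*X_total + b*S_Ca) / S_fa`:
#' `K = K_ifa*R / (K_ifa*R + S_fa)`, evaluated in the algebraically
#' equivalent form `K_ifa*C / (K_ifa*C + S_fa^2)` with
#' `C = a*X_total + b*S_Ca`, whose limit for `S_fa -> 0` is finite and equal
#' to 1 (no LCFA, no inhibition). With no biomass and no calcium but LCFA
#' present the factor is 0 (full inhibition).
#'
#' @param K_ifa Inhibition constant, kg COD/m^3 (strictly positive).
#' @param a,b Dimensionless weights on biomass and calcium equivalent.
#' @param X_total Total active biomass `X_h + X_v + X_m`, kg COD/m^3.
#' @param S_Ca Calcium binding equivalent, kg COD/m^3.
#' @param S_fa LCFA concentration, kg COD/m^3.
#' @return Numeric in \[0, 1\]; vectorized over the state arguments.
#' @examples
#' inhibition_factor(5, 0.5, 0.5, X_total = 2, S_Ca = 0, S_fa = 9.9)
#' inhibition_factor(5, 0.5, 0.5, X_total = 3, S_Ca = 0, S_fa = 0)  # 1
#' @export
inhibition_factor <- function(K_ifa, a, b, X_total, S_Ca, S_fa) {
  vals <- c(K_ifa, a, b, X_total, S_Ca, S_fa)
  if (any(!is.finite(vals)))
    stop("inhibition_factor: all inputs must be finite")
  if (any(vals < 0))
    stop("inhibition_factor: all inputs must be non-negative")
  if (any(K_ifa <= 0))
    stop("inhibition_factor: K_ifa must be strictly positive")
  .inhib(K_ifa, a * X_total + b * S_Ca, S_fa)
}

#' Inhibition factors for the three functional groups
#'
#' Applies [inhibition_factor()] with the group-specific constants `Khfa`,
#' `Kvfa`, `Kmfa` and `X_total = X_h + X_v + X_m`. Because the factor is
#' increasing in its constant, `Khfa >= Kvfa >= Kmfa` implies
#' `K_h >= K_v >= K_m` at any state.
#'
#' @param params An [ad_params()] object.
#' @param state A [model_state()] vector.
#' @return Named numeric `c(K_h, K_v, K_m)`, each in \[0, 1\].
#' @export
compute_inhibition <- function(params, state) {
  validate_params(params)
  state <- do.call(model_state, as.list(state[.state_order]))
  X_total <- sum(state[c("X_h", "X_v", "X_m")])
  k <- vapply(c("Khfa", "Kvfa", "Kmfa"), function(nm)
    inhibition_factor(params[[nm]], params$a, params$b,
                      X_total, state[["S_Ca"]], state[["S_fa"]]),
    numeric(1))
  setNames(k, c("K_h", "K_v", "K_m"))
}
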