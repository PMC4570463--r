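# Batch experiment setup: substrate/inoculum specifications, initial states,
# methane curves, specific methane production and response-surface sweeps.

#' Substrate specification
#'
#' Composition of a digestion substrate. `substrate_ns1()` and
#' `substrate_ns2()` return the two built-in algal substrates: whole
#' *Nannochloropsis salina* biomass (high lipid) and its lipid-extracted
#' residue (low lipid). The default COD density of 2.83 g COD/g VS is the
#' value that makes the potential-LCFA calculation reproduce both reported
#' digester LCFA concentrations (9.9 and 3.1 g COD/L at 10 g VS/L loading).
#'
#' @param name Substrate label.
#' @param lipid,carbohydrate,protein,unknown Fractions of dry mass, percent.
#' @param vs_ts Volatile/total solids ratio, percent.
#' @param f_fa Fatty-acid fraction of hydrolysis products (dimensionless).
#' @param cod_vs Substrate COD per volatile solid, g COD/g VS.
#' @return List of class `substrate_spec`.
#' @export
substrate_spec <- function(name, lipid, carbohydrate, protein, unknown,
                           vs_ts, f_fa, cod_vs = 2.83) {
  fr <- c(lipid, carbohydrate, protein, unknown, vs_ts)
  if (any(fr < 0 | fr > 100)) stop("composition fractions must be in [0, 100]")
  if (f_fa < 0 || f_fa > 1) stop("f_fa must be in [0, 1]")
  if (cod_vs <= 0) stop("cod_vs must be positive")
  structure(list(name = name, lipid = lipid, carbohydrate = carbohydrate,
                 protein = protein, unknown = unknown, vs_ts = vs_ts,
                 f_fa = f_fa, cod_vs = cod_vs),
            class = "substrate_spec")
}

#' @rdname substrate_spec
#' @export
substrate_ns1 <- function() {
  substrate_spec("NS1", lipid = 37.2, carbohydrate = 11.5, protein = 17.2,
                 unknown = 27.2, vs_ts = 93.0, f_fa = 0.35)
}

#' @rdname substrate_spec
#' @export
substrate_ns2 <- function() {
  substrate_spec("NS2", lipid = 11.8, carbohydrate = 17.0, protein = 26.7,
                 unknown = 34.1, vs_ts = 89.7, f_fa = 0.11)
}

#' Inoculum specification
#'
#' Anaerobic sludge used to seed the batches. Defaults describe a municipal
#' digester sludge (TS 17.1 g/L, VS 11.7 g/L) with a biomass COD density of
#' 1.42 g COD/g VS, all of it active, split 65/30/5 between hydrolytic
#' bacteria, acidogens and methanogens — digester communities are dominated
#' by hydrolytic/fermentative bacteria while methanogenic archaea are a
#' small minority of the biomass. The active fraction and split are
#' modelling conventions (the assay does not resolve them) and are
#' configurable.
#'
#' @param ts,vs Total and volatile solids of the sludge, g/L (`vs <= ts`).
#' @param cod_vs Biomass COD per volatile solid, g COD/g VS.
#' @param active_fraction Fraction of inoculum COD that is active biomass.
#' @param split Fractions of active COD assigned to `X_h`, `X_v`, `X_m`;
#'   must sum to 1.
#' @return List of class `inoculum_spec`.
#' @export
inoculum_spec <- function(ts = 17.1, vs = 11.7, cod_vs = 1.42,
                          active_fraction = 1,
                          split = c(X_h = 0.65, X_v = 0.30, X_m = 0.05)) {
  if (vs > ts) stop("inoculum VS cannot exceed TS")
  if (cod_vs <= 0) stop("cod_vs must be positive")
  if (active_fraction < 0 || active_fraction > 1)
    stop("active_fraction must be in [0, 1]")
  if (length(split) != 3 || abs(sum(split) - 1) > 1e-8)
    stop("split must have 3 elements summing to 1")
  structure(list(ts = ts, vs = vs, cod_vs = cod_vs,
                 active_fraction = active_fraction,
                 split = setNames(as.numeric(split), c("X_h", "X_v", "X_m"))),
            class = "inoculum_spec")
}

#' Batch configuration
#'
#' One BMP bottle: organic loading, inoculum-to-substrate ratio (VS basis),
#' calcium-to-lipid molar dose, duration and temperature. The study design
#' is 10 g VS/L loading, I/S in \{0.1, 0.4, 1.0\}, calcium ratio in
#' \{0, 0.5, 1, 2\}, 35 deg C for 20 days.
#'
#' @param loading Organic loading, g VS/L.
#' @param is_ratio Inoculum-to-substrate ratio, g VS/g VS.
#' @param ca_ratio Calcium : lipid-LCFA molar ratio (dimensionless).
#' @param duration Days.
#' @param temperature Deg C (recorded; the kinetics are for 35 deg C).
#' @return List of class `batch_config`.
#' @export
batch_config <- function(loading = 10, is_ratio = 1, ca_ratio = 0,
                         duration = 20, temperature = 35) {
  if (loading <= 0) stop("loading must be positive")
  if (is_ratio < 0) stop("is_ratio must be non-negative")
  if (ca_ratio < 0) stop("ca_ratio must be non-negative")
  if (duration <= 0) stop("duration must be positive")
  structure(list(loading = loading, is_ratio = is_ratio, ca_ratio = ca_ratio,
                 duration = duration, temperature = temperature),
            class = "batch_config")
}

#' Unit conversions
#'
#' @param ch4_per_cod Methane volume per COD converted, L CH4/g COD
#'   (0.35 at STP; 0.395 at 35 deg C).
#' @param lcfa_cod_per_mol COD of one mole of a representative LCFA
#'   (oleate: 816 g COD/mol), used when expressing molar doses.
#' @return List of class `unit_conversions`.
#' @export
unit_conversions <- function(ch4_per_cod = 0.35, lcfa_cod_per_mol = 816) {
  if (ch4_per_cod <= 0 || lcfa_cod_per_mol <= 0)
    stop("conversions must be positive")
  structure(list(ch4_per_cod = ch4_per_cod,
                 lcfa_cod_per_mol = lcfa_cod_per_mol),
            class = "unit_conversions")
}

#' Potential LCFA concentration of a batch
#'
#' The LCFA COD liberated if all substrate hydrolyses:
#' `f_fa * loading * cod_vs`. For whole algal biomass at 10 g VS/L this is
#' 9.9 g COD/L and for the lipid-extracted residue 3.1 g COD/L.
#'
#' @param substrate A [substrate_spec()].
#' @param config A [batch_config()].
#' @return kg COD/m^3 (g COD/L).
#' @export
potential_lcfa <- function(substrate, config) {
  substrate$f_fa * config$loading * substrate$cod_vs
}

#' Calcium LCFA-binding equivalent
#'
#' One calcium ion binds two LCFA molecules, so a molar dose of `ca_ratio`
#' times the LCFA pool neutralises `2 * ca_ratio` of it. The equivalent is
#' expressed on the COD scale of the LCFA pool: `S_Ca = 2 * ca_ratio *
#' lcfa_potential`, so the 0.5 mol/mol dose exactly covers the pool.
#'
#' @param ca_ratio Calcium : LCFA molar ratio, >= 0.
#' @param lcfa_potential Potential LCFA, kg COD/m^3.
#' @return `S_Ca`, kg COD/m^3.
#' @export
calcium_equivalent <- function(ca_ratio, lcfa_potential) {
  if (any(ca_ratio < 0) || any(lcfa_potential < 0))
    stop("ca_ratio and lcfa_potential must be non-negative")
  2 * ca_ratio * lcfa_potential
}

#' Initial model state of a batch
#'
#' Particulate substrate is the full substrate COD (`loading * cod_vs`);
#' soluble pools and methane start at zero; inoculum COD
#' (`is_ratio * loading * inoculum cod_vs * active_fraction`) is split into
#' the three biomass groups; the calcium equivalent comes from
#' [calcium_equivalent()].
#'
#' @param substrate A [substrate_spec()].
#' @param inoculum An [inoculum_spec()].
#' @param config A [batch_config()].
#' @return A [model_state()] vector.
#' @export
initial_state <- function(substrate, inoculum, config) {
  x_cod <- config$is_ratio * config$loading * inoculum$cod_vs *
    inoculum$active_fraction
  x <- x_cod * inoculum$split
  model_state(S_p = config$loading * substrate$cod_vs,
              X_h = x[["X_h"]], X_v = x[["X_v"]], X_m = x[["X_m"]],
              S_Ca = calcium_equivalent(config$ca_ratio,
                                        potential_lcfa(substrate, config)))
}

#' Cumulative methane volume curve from a trajectory
#'
#' Converts the methane COD pool to volume per working volume
#' (`S_m * ch4_per_cod`, L CH4/L) and samples at whole days.
#'
#' @param trajectory An `ad_trajectory`.
#' @param conversions A [unit_conversions()].
#' @return Data frame of class `methane_curve` with columns `day`,
#'   `cumulative_CH4_L_per_L`.
#' @export
methane_curve <- function(trajectory, conversions = unit_conversions()) {
  t <- trajectory$time_d
  keep <- abs(t - round(t)) < 1e-9
  if (!any(keep)) stop("trajectory has no whole-day reporting points")
  out <- data.frame(day = as.integer(round(t[keep])),
                    cumulative_CH4_L_per_L =
                      trajectory$S_m[keep] * conversions$ch4_per_cod)
  class(out) <- c("methane_curve", "data.frame")
  out
}

#' Specific methane production
#'
#' Final cumulative methane volume divided by the organic loading.
#'
#' @param curve A `methane_curve`.
#' @param loading Organic loading, g VS/L (> 0).
#' @return L CH4/g VS.
#' @export
smp <- function(curve, loading) {
  if (loading <= 0) stop("loading must be strictly positive")
  curve$cumulative_CH4_L_per_L[nrow(curve)] / loading
}

#' Response surface of SMP over biomass:LCFA and Ca:LCFA ratios
#'
#' Runs one full simulation per grid point. The biomass axis is the initial
#' active inoculum COD expressed as a fraction of the potential LCFA COD
#' (the inoculum split follows `inoculum$split`); the calcium axis is the
#' molar Ca:LCFA dose. Integration failures are flagged per cell rather than
#' aborting the sweep.
#'
#' @param substrate A [substrate_spec()].
#' @param inoculum An [inoculum_spec()] (only the split is used).
#' @param params An [ad_params()] set; its `f_fa` is overridden by the
#'   substrate's.
#' @param biomass_ratios,ca_ratios Grid axes (non-empty, non-negative).
#' @param loading Organic loading, g VS/L.
#' @param duration Days.
#' @param conversions A [unit_conversions()].
#' @return Long-format data frame `biomass_ratio, ca_ratio, smp, ok`.
#' @export
smp_sweep <- function(substrate, inoculum, params,
                      biomass_ratios = seq(0, 1.5, length.out = 5),
                      ca_ratios = seq(0, 2, length.out = 5),
                      loading = 10, duration = 20,
                      conversions = unit_conversions()) {
  if (!length(biomass_ratios) || !length(ca_ratios))
    stop("grid axes must be non-empty")
  params$f_fa <- substrate$f_fa
  validate_params(params)
  lcfa <- potential_lcfa(substrate, batch_config(loading = loading,
                                                 is_ratio = 0))
  grid <- expand.grid(biomass_ratio = biomass_ratios, ca_ratio = ca_ratios,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- grid$biomass_ratio[i] * lcfa * inoculum$split
    s0 <- model_state(S_p = loading * substrate$cod_vs,
                      X_h = x[["X_h"]], X_v = x[["X_v"]], X_m = x[["X_m"]],
                      S_Ca = calcium_equivalent(grid$ca_ratio[i], lcfa))
    tryCatch({
      traj <- simulate_ad(params, s0, t_end = duration, report_step = 1)
      c(smp(methane_curve(traj, conversions), loading), TRUE)
    }, error = function(e) c(NA_real_, FALSE))
  })
  grid$smp <- vapply(res, `[`, numeric(1), 1)
  grid$ok <- as.logical(vapply(res, `[`, numeric(1), 2))
  grid
}
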