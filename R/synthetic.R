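# Synthetic BMP study generator: daily cumulative methane curves with known
# ground truth, for calibration and sensitivity testing.

#' Experimental design grid
#'
#' The batch configurations of the study design: every combination of
#' substrate, inoculum-to-substrate ratio and calcium dose, at a common
#' loading and duration.
#'
#' @param substrates List of [substrate_spec()]s.
#' @param is_ratios Inoculum-to-substrate ratios, g VS/g VS.
#' @param ca_ratios Calcium : LCFA molar ratios.
#' @param loading Organic loading, g VS/L.
#' @param duration Days.
#' @return List of `list(label, substrate, config)` entries.
#' @export
study_configs <- function(substrates = list(substrate_ns1(), substrate_ns2()),
                          is_ratios = c(0.1, 0.4, 1.0),
                          ca_ratios = c(0, 0.5, 1, 2),
                          loading = 10, duration = 20) {
  out <- list()
  for (sub in substrates)
    for (is_r in is_ratios)
      for (ca_r in ca_ratios)
        out[[length(out) + 1L]] <- list(
          label = sprintf("%s_is%g_ca%g", sub$name, is_r, ca_r),
          substrate = sub,
          config = batch_config(loading = loading, is_ratio = is_r,
                                ca_ratio = ca_r, duration = duration))
  out
}

#' Generate a synthetic BMP study
#'
#' Simulates every configuration at the true parameters, samples the
#' cumulative methane curve daily, and perturbs the *daily increments* with
#' multiplicative Gaussian noise (relative s.d. `noise_sd_rel`), clipping
#' negative increments to zero before re-cumulating — so every generated
#' curve is non-negative and non-decreasing regardless of the noise level.
#' Regeneration with the same seed is bit-identical; the RNG state of the
#' caller is restored on exit.
#'
#' @param true_params Ground-truth [ad_params()] (each substrate's `f_fa`
#'   overrides the set's).
#' @param configs Design list from [study_configs()].
#' @param inoculum An [inoculum_spec()].
#' @param conversions A [unit_conversions()].
#' @param noise_sd_rel Relative s.d. of the increment noise (>= 0;
#'   default 0.05).
#' @param seed Integer seed.
#' @return List of class `bmp_study`: `true_params`, `configs`, `curves`
#'   (one `methane_curve` per config), `trajectories` (noiseless ground
#'   truth), `ok` (per-config success flag), `noise_sd_rel`, `seed`,
#'   plus the inoculum and conversions used.
#' @export
generate_bmp_study <- function(true_params = ad_params(),
                               configs = study_configs(),
                               inoculum = inoculum_spec(),
                               conversions = unit_conversions(),
                               noise_sd_rel = 0.05, seed = 1L) {
  if (noise_sd_rel < 0) stop("noise_sd_rel must be non-negative")
  validate_params(true_params)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  curves <- vector("list", length(configs))
  trajs <- vector("list", length(configs))
  ok <- logical(length(configs))
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    params <- true_params
    params$f_fa <- cf$substrate$f_fa
    res <- tryCatch({
      s0 <- initial_state(cf$substrate, inoculum, cf$config)
      traj <- simulate_ad(params, s0, t_end = cf$config$duration,
                          report_step = 1)
      curve <- methane_curve(traj, conversions)
      inc <- diff(curve$cumulative_CH4_L_per_L)
      if (noise_sd_rel > 0) {
        inc <- pmax(0, inc * (1 + rnorm(length(inc), 0, noise_sd_rel)))
        curve$cumulative_CH4_L_per_L <-
          c(curve$cumulative_CH4_L_per_L[1],
            curve$cumulative_CH4_L_per_L[1] + cumsum(inc))
      }
      list(curve = curve, traj = traj)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      ok[i] <- FALSE
      warning("config ", cf$label, " failed: ", conditionMessage(res),
              call. = FALSE)
    } else {
      ok[i] <- TRUE
      curves[[i]] <- res$curve
      trajs[[i]] <- res$traj
    }
  }
  structure(list(true_params = true_params, configs = configs,
                 inoculum = inoculum, conversions = conversions,
                 curves = curves, trajectories = trajs, ok = ok,
                 noise_sd_rel = noise_sd_rel, seed = seed),
            class = "bmp_study")
}

#' @export
print.bmp_study <- function(x, ...) {
  cat("Synthetic BMP study:", length(x$configs), "configurations (",
      sum(x$ok), "simulated ), noise sd", x$noise_sd_rel,
      ", seed", x$seed, "\n")
  invisible(x)
}

#' Convert a study to calibration datasets
#'
#' @param study A `bmp_study`.
#' @return List of [bmp_dataset()]s (failed configurations are dropped).
#' @export
study_datasets <- function(study) {
  idx <- which(study$ok)
  lapply(idx, function(i)
    bmp_dataset(study$configs[[i]]$config, study$curves[[i]],
                study$configs[[i]]$substrate, study$inoculum,
                study$conversions))
}

#' Write a study to disk
#'
#' One curve file per configuration (`curve_<label>.tsv`), a manifest
#' (`manifest.tsv` with columns `label, substrate, loading, is_ratio,
#' ca_ratio, duration, curve_file`) and the ground-truth parameter file
#' (`true_params.yml`).
#'
#' @param study A `bmp_study`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- which(study$ok)
  rows <- lapply(idx, function(i) {
    cf <- study$configs[[i]]
    file <- sprintf("curve_%s.tsv", cf$label)
    write_methane_curve(study$curves[[i]], file.path(dir, file))
    data.frame(label = cf$label, substrate = cf$substrate$name,
               loading = cf$config$loading, is_ratio = cf$config$is_ratio,
               ca_ratio = cf$config$ca_ratio,
               duration = cf$config$duration, curve_file = file)
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(manifest, manifest_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  write_params(study$true_params, file.path(dir, "true_params.yml"))
  invisible(manifest_path)
}
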