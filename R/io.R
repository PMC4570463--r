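# Delimited-text I/O for methane curves, sweeps and run manifests.

#' Read / write a cumulative methane curve
#'
#' Curves are tab-separated text with header columns `day` and
#' `cumulative_CH4_L_per_L`. Reading validates the series: numeric values,
#' strictly increasing days without duplicates, non-negative and
#' non-decreasing cumulative volumes; violations raise an error naming the
#' offending line (header is line 1).
#'
#' @param path File path.
#' @return `read_methane_curve()` returns a `methane_curve` data frame.
#' @export
read_methane_curve <- function(path) {
  df <- read.delim(path, sep = "\t", colClasses = "character")
  if (!identical(names(df), c("day", "cumulative_CH4_L_per_L")))
    stop("expected columns: day, cumulative_CH4_L_per_L")
  day <- suppressWarnings(as.numeric(df$day))
  vol <- suppressWarnings(as.numeric(df$cumulative_CH4_L_per_L))
  bad <- which(!is.finite(day) | !is.finite(vol))
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1L, " of ", path)
  dup <- which(duplicated(day))
  if (length(dup))
    stop("duplicate day at line ", dup[1] + 1L, " of ", path)
  nonmono_day <- which(diff(day) <= 0)
  if (length(nonmono_day))
    stop("days not strictly increasing at line ", nonmono_day[1] + 2L,
         " of ", path)
  if (any(vol < 0))
    stop("negative cumulative value at line ", which(vol < 0)[1] + 1L,
         " of ", path)
  dec <- which(diff(vol) < 0)
  if (length(dec))
    stop("decreasing cumulative value at line ", dec[1] + 2L, " of ", path)
  out <- data.frame(day = day, cumulative_CH4_L_per_L = vol)
  class(out) <- c("methane_curve", "data.frame")
  out
}

#' @rdname read_methane_curve
#' @param curve A `methane_curve`.
#' @export
write_methane_curve <- function(curve, path) {
  # %.17g keeps write/read a bit-exact round trip for doubles
  out <- data.frame(day = curve$day,
                    cumulative_CH4_L_per_L =
                      sprintf("%.17g", curve$cumulative_CH4_L_per_L))
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a sweep surface as long-format delimited text
#'
#' @param sweep Data frame from [smp_sweep()].
#' @param path Output path.
#' @export
write_sweep <- function(sweep, path) {
  write.table(sweep[, c("biomass_ratio", "ca_ratio", "smp")], path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Built-in substrates addressable by name in manifests and the CLI.
.substrate_by_name <- function(name) {
  switch(toupper(name),
         NS1 = substrate_ns1(),
         NS2 = substrate_ns2(),
         stop("unknown substrate: ", name, " (expected NS1 or NS2)"))
}

#' Read a run manifest into calibration datasets
#'
#' The manifest is tab-separated with columns `label, substrate, loading,
#' is_ratio, ca_ratio, duration, curve_file` (as written by [write_study()]);
#' curve paths are resolved relative to the manifest's directory and must
#' exist.
#'
#' @param path Manifest path.
#' @param inoculum An [inoculum_spec()] applied to every dataset.
#' @param conversions A [unit_conversions()] applied to every dataset.
#' @return List of [bmp_dataset()]s.
#' @export
read_manifest <- function(path, inoculum = inoculum_spec(),
                          conversions = unit_conversions()) {
  mf <- read.delim(path, sep = "\t")
  need <- c("label", "substrate", "loading", "is_ratio", "ca_ratio",
            "duration", "curve_file")
  if (!all(need %in% names(mf)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(path)
  lapply(seq_len(nrow(mf)), function(i) {
    curve_path <- file.path(base, mf$curve_file[i])
    if (!file.exists(curve_path))
      stop("curve file does not exist: ", curve_path)
    bmp_dataset(batch_config(loading = mf$loading[i],
                             is_ratio = mf$is_ratio[i],
                             ca_ratio = mf$ca_ratio[i],
                             duration = mf$duration[i]),
                read_methane_curve(curve_path),
                .substrate_by_name(mf$substrate[i]),
                inoculum, conversions)
  })
}
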