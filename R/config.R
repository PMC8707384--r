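#' Screening run configuration
#'
#' Bundles every tunable threshold and tolerance used across the pipeline
#' into a single validated list, so that filter decisions are reproducible
#' and auditable.
#'
#' Defaults mirror the screening conventions of the source assays:
#' radical-scavenging cutoff 50\%, in vitro SPF cutoff 2, broad-spectrum
#' requirement of critical wavelength above 370 nm together with a
#' UVA/UVB ratio of at least 0.7, non-toxicity above 75\% viability at the
#' top test dose, a 10 ppm mass-accuracy window and 0.2 min retention-time
#' window for LC-MS feature matching, and a 330 Da molecular-weight
#' threshold below which skin permeation is considered likely.
#'
#' @param wavelength_step_nm Resampling grid step for spectra, in nm.
#' @param spf_band Inclusive UV-B band used by the SPF sum, in nm.
#' @param full_band Inclusive full UV band recorded, in nm.
#' @param rsc_cutoff_pct Radical-scavenging selection cutoff (\%).
#' @param spfi_cutoff In vitro SPF selection cutoff (dimensionless).
#' @param spfi_active_cutoff "Most-active" SPFi tier (dimensionless);
#'   reported but not used for selection.
#' @param lambda_c_cutoff_nm Critical-wavelength cutoff for a broad-spectrum
#'   claim, in nm (strict inequality).
#' @param uva_uvb_cutoff UVA/UVB-ratio cutoff (inclusive).
#' @param viability_cutoff_pct Non-toxicity cutoff on cell viability at the
#'   top dose (\%, strict inequality).
#' @param ppm_tolerance Mass-accuracy window for feature matching and
#'   annotation, in ppm.
#' @param rt_tolerance_min Retention-time window for feature matching, in
#'   minutes.
#' @param mw_threshold_da Mass threshold for the permeation-relevant
#'   fraction, in Da.
#' @param spfi_reference Reference-filter SPFi used to express SPFi as a
#'   percentage on the radar chart (the benchmark organic UV filter measured
#'   at 30 ug/mL); `NA` disables normalization.
#' @param rng_seed Integer seed recorded with the run.
#'
#' @return An object of class `run_config` (a named list).
#' @examples
#' cfg <- run_config()
#' cfg$spfi_cutoff
#' @export
run_config <- function(wavelength_step_nm = 1,
                       spf_band = c(290, 320),
                       full_band = c(290, 400),
                       rsc_cutoff_pct = 50,
                       spfi_cutoff = 2,
                       spfi_active_cutoff = 5,
                       lambda_c_cutoff_nm = 370,
                       uva_uvb_cutoff = 0.7,
                       viability_cutoff_pct = 75,
                       ppm_tolerance = 10,
                       rt_tolerance_min = 0.2,
                       mw_threshold_da = 330,
                       spfi_reference = NA_real_,
                       rng_seed = 1L) {
  cfg <- list(
    wavelength_step_nm = as.numeric(wavelength_step_nm),
    spf_band = as.numeric(spf_band),
    full_band = as.numeric(full_band),
    rsc_cutoff_pct = as.numeric(rsc_cutoff_pct),
    spfi_cutoff = as.numeric(spfi_cutoff),
    spfi_active_cutoff = as.numeric(spfi_active_cutoff),
    lambda_c_cutoff_nm = as.numeric(lambda_c_cutoff_nm),
    uva_uvb_cutoff = as.numeric(uva_uvb_cutoff),
    viability_cutoff_pct = as.numeric(viability_cutoff_pct),
    ppm_tolerance = as.numeric(ppm_tolerance),
    rt_tolerance_min = as.numeric(rt_tolerance_min),
    mw_threshold_da = as.numeric(mw_threshold_da),
    spfi_reference = as.numeric(spfi_reference),
    rng_seed = as.integer(rng_seed)
  )
  num <- cfg[setdiff(names(cfg), "spfi_reference")]
  if (!all(vapply(num, function(x) all(is.finite(x)), logical(1L))))
    stop("run_config: all cutoffs and tolerances must be finite", call. = FALSE)
  if (cfg$wavelength_step_nm <= 0)
    stop("run_config: wavelength_step_nm must be positive", call. = FALSE)
  if (length(cfg$spf_band) != 2L || length(cfg$full_band) != 2L ||
      diff(cfg$spf_band) <= 0 || diff(cfg$full_band) <= 0)
    stop("run_config: bands must be increasing length-2 ranges", call. = FALSE)
  if (cfg$spf_band[1L] < cfg$full_band[1L] || cfg$spf_band[2L] > cfg$full_band[2L])
    stop("run_config: spf_band must lie within full_band", call. = FALSE)
  if (cfg$ppm_tolerance <= 0)
    stop("run_config: ppm_tolerance must be > 0", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = "..")))
  invisible(x)
}

# Append filter decisions to a machine-readable audit trail.
# `decisions` is a data.frame with columns id, criterion, value, threshold, pass.
write_audit_log <- function(decisions, path, append = FALSE) {
  stopifnot(is.data.frame(decisions))
  utils::write.table(decisions, path, sep = "\t", row.names = FALSE,
                     col.names = !append || !file.exists(path),
                     append = append && file.exists(path), quote = FALSE)
  invisible(path)
}
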