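#' Radical scavenging capacity from blank and sample absorbances
#'
#' `RSC(%) = 100 * (mean(A_C) - mean(A_S)) / mean(A_C)`, where `A_C` is the
#' blank (radical solution plus solvent) and `A_S` the radical solution
#' incubated with the sample. Replicates are aggregated by arithmetic mean
#' before the ratio; the SD is computed over per-replicate RSC values
#' against the blank mean. Negative values (pro-oxidant behaviour or
#' assay interference) are preserved and flagged, never clipped.
#'
#' @param a_c Numeric vector of blank absorbance replicates.
#' @param a_s Numeric vector of sample absorbance replicates.
#' @return List with `rsc_pct`, `sd_pct`, `n`, and logical `negative`.
#' @examples
#' radical_scavenging(c(0.70, 0.70, 0.70), c(0.35, 0.36, 0.34))$rsc_pct
#' @export
radical_scavenging <- function(a_c, a_s) {
  a_c <- as.numeric(a_c); a_s <- as.numeric(a_s)
  if (length(a_c) < 1L || length(a_s) < 1L || anyNA(a_c) || anyNA(a_s))
    stop("blank and sample replicates must be nonempty and NA-free", call. = FALSE)
  ac <- mean(a_c)
  if (ac <= 0)
    stop("assay error: blank mean absorbance must be positive", call. = FALSE)
  per_rep <- 100 * (ac - a_s) / ac
  rsc <- mean(per_rep)
  list(rsc_pct = rsc,
       sd_pct = if (length(a_s) > 1L) stats::sd(per_rep) else NA_real_,
       n = length(a_s),
       negative = rsc < 0)
}

#' Linear standard (calibration) curve
#'
#' Holds slope and intercept of a linear response curve
#' `response = slope * concentration + intercept` together with the
#' calibrated concentration range.
#'
#' @param slope,intercept Curve coefficients (response per concentration
#'   unit; response units).
#' @param analyte Analyte label, e.g. `"Trolox-DPPH"`, `"gallic-acid"`.
#' @param valid_range Calibrated concentration interval `c(lo, hi)`.
#' @param r_squared Optional goodness of fit.
#' @return Object of class `standard_curve`.
#' @export
standard_curve <- function(slope, intercept, analyte = "analyte",
                           valid_range = c(-Inf, Inf), r_squared = NA_real_) {
  if (!is.finite(slope) || slope == 0)
    stop("standard_curve: slope must be nonzero and finite", call. = FALSE)
  structure(list(slope = slope, intercept = intercept, analyte = analyte,
                 valid_range = as.numeric(valid_range), r_squared = r_squared),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> %s: Y = %.4g X %+.4g (R^2 = %s)\n",
              x$analyte, x$slope, x$intercept,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  invisible(x)
}

#' Published Trolox calibration curves for the DPPH and ABTS assays
#'
#' The calibration curves mapping Trolox concentration X (umol/L) to
#' radical-scavenging response Y (\%): DPPH `Y = 2.167 X - 0.5203`, ABTS
#' `Y = 3.066 X - 1.356`. With these curves, an extract at 5 g/L reaching
#' 50\% scavenging corresponds to TEAC 4.66 (DPPH) and 3.35 (ABTS)
#' umol TE/g dry weight.
#'
#' @param assay `"DPPH"` or `"ABTS"`.
#' @return A [standard_curve()].
#' @export
trolox_curve <- function(assay = c("DPPH", "ABTS")) {
  assay <- match.arg(assay)
  if (assay == "DPPH")
    standard_curve(2.167, -0.5203, analyte = "Trolox-DPPH")
  else
    standard_curve(3.066, -1.356, analyte = "Trolox-ABTS")
}

#' Trolox-equivalent antioxidant capacity
#'
#' Inverts the Trolox calibration curve at the measured scavenging
#' response and normalizes by the extract concentration:
#' `T (umol/L) = (RSC - intercept) / slope`, `TEAC = T / S` with S the
#' sample concentration in g/L, giving umol TE per gram dry weight.
#'
#' @param rsc Radical-scavenging capacity (\%).
#' @param curve A [standard_curve()] (default the published DPPH Trolox
#'   curve).
#' @param sample_conc Sample concentration S in g/L.
#' @return List with `teac` (umol TE/g_DW), `trolox_umol_l`, and
#'   `extrapolated` (TRUE when the response falls outside the calibrated
#'   range).
#' @examples
#' teac(50, trolox_curve("DPPH"), 5)$teac  # 4.66
#' @export
teac <- function(rsc, curve = trolox_curve("DPPH"), sample_conc) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.finite(sample_conc) || sample_conc <= 0)
    stop("teac: sample concentration must be positive", call. = FALSE)
  t_conc <- (rsc - curve$intercept) / curve$slope
  resp_range <- sort(curve$slope * curve$valid_range + curve$intercept)
  list(teac = t_conc / sample_conc,
       trolox_umol_l = t_conc,
       extrapolated = is.finite(resp_range[1L]) &&
         (rsc < resp_range[1L] || rsc > resp_range[2L]))
}

#' Inverse of [teac()]: the scavenging response implied by a TEAC value
#'
#' @param teac_value TEAC in umol TE/g_DW.
#' @param curve A [standard_curve()].
#' @param sample_conc Sample concentration in g/L.
#' @return RSC (\%).
#' @export
rsc_from_teac <- function(teac_value, curve = trolox_curve("DPPH"), sample_conc) {
  stopifnot(inherits(curve, "standard_curve"), sample_conc > 0)
  teac_value * sample_conc * curve$slope + curve$intercept
}

#' Fit a linear standard curve by ordinary least squares
#'
#' @param concentrations Standard concentrations (>= 3 distinct values).
#' @param responses Measured responses, same length.
#' @param analyte Analyte label.
#' @return A [standard_curve()] with `r_squared`; warns when R^2 < 0.98.
#' @export
fit_standard_curve <- function(concentrations, responses, analyte = "analyte") {
  x <- as.numeric(concentrations); y <- as.numeric(responses)
  if (length(x) != length(y) || anyNA(x) || anyNA(y))
    stop("concentrations and responses must be NA-free and equal length", call. = FALSE)
  if (length(unique(x)) < 3L)
    stop("fit error: need at least 3 distinct standard concentrations", call. = FALSE)
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  if (r2 < 0.98)
    warning(sprintf("standard curve R^2 = %.4f < 0.98", r2), call. = FALSE)
  standard_curve(stats::coef(fit)[["x"]], stats::coef(fit)[["(Intercept)"]],
                 analyte = analyte, valid_range = range(x), r_squared = r2)
}

#' Equivalent content (TPC/TFC) from a standard curve
#'
#' Converts an assay response into equivalents of the calibration analyte
#' (gallic acid for total phenolics, quercetin for total flavonoids) per
#' 100 g of extract dry weight: `C_eq (ug/mL) = (response - intercept) /
#' slope`; `content (mg eq / 100 g_DW) = C_eq / S * 100` with S in g/L.
#' Responses below the lowest calibrated standard are reported as not
#' detected.
#'
#' @param response Measured assay response (mean over replicates).
#' @param curve A [standard_curve()] calibrated in ug/mL.
#' @param sample_conc Extract concentration S in g/L.
#' @return List with `content_mg_per_100g`, `c_eq_ug_ml`,
#'   `below_detection`.
#' @export
equivalents_content <- function(response, curve, sample_conc) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.finite(sample_conc) || sample_conc <= 0)
    stop("equivalents_content: sample concentration must be positive", call. = FALSE)
  c_eq <- (response - curve$intercept) / curve$slope
  below <- is.finite(curve$valid_range[1L]) && c_eq < curve$valid_range[1L]
  # S g/L = S * 1000 ug/mL; scale to "per 100 g dry weight":
  # C_eq / (S*1000) * 1e5 = C_eq / S * 100
  list(content_mg_per_100g = if (below) NA_real_ else c_eq / sample_conc * 100,
       c_eq_ug_ml = c_eq,
       below_detection = below)
}

#' Antioxidant summary for one sample across assay plates
#'
#' Runs [radical_scavenging()] and [teac()] for DPPH and ABTS plates and,
#' when given, [equivalents_content()] for TPC/TFC plates.
#'
#' @param plates Named list of plates from [read_plate_table()] or
#'   [make_plates()], with elements among `DPPH`, `ABTS`, `TPC`, `TFC`.
#' @param sample_id Sample to summarize.
#' @param sample_conc Extract concentration in g/L.
#' @param tpc_curve,tfc_curve Optional [standard_curve()]s (ug/mL) for the
#'   phenolic and flavonoid assays.
#' @return One-row data.frame of antioxidant metrics.
#' @export
antioxidant_summary <- function(plates, sample_id, sample_conc = 5,
                                tpc_curve = NULL, tfc_curve = NULL) {
  get_rsc <- function(assay) {
    p <- plates[[assay]]
    if (is.null(p)) return(list(rsc_pct = NA_real_, sd_pct = NA_real_))
    radical_scavenging(p$blank_abs, p$sample_abs[[sample_id]])
  }
  dpph <- get_rsc("DPPH"); abts <- get_rsc("ABTS")
  out <- data.frame(
    sample_id = sample_id,
    rsc_dpph = dpph$rsc_pct, rsc_dpph_sd = dpph$sd_pct,
    rsc_abts = abts$rsc_pct, rsc_abts_sd = abts$sd_pct,
    teac_dpph = if (is.na(dpph$rsc_pct)) NA_real_ else
      teac(dpph$rsc_pct, trolox_curve("DPPH"), sample_conc)$teac,
    teac_abts = if (is.na(abts$rsc_pct)) NA_real_ else
      teac(abts$rsc_pct, trolox_curve("ABTS"), sample_conc)$teac,
    stringsAsFactors = FALSE
  )
  for (nm in c("TPC", "TFC")) {
    curve <- if (nm == "TPC") tpc_curve else tfc_curve
    col <- tolower(nm)
    p <- plates[[nm]]
    if (!is.null(p) && !is.null(curve)) {
      eq <- equivalents_content(mean(p$sample_abs[[sample_id]]), curve, sample_conc)
      out[[col]] <- eq$content_mg_per_100g
      out[[paste0(col, "_below_detection")]] <- eq$below_detection
    } else {
      out[[col]] <- NA_real_
      out[[paste0(col, "_below_detection")]] <- NA
    }
  }
  out
}
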