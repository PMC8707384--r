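#' Erythemal weighting constants for the Mansur in vitro SPF
#'
#' The product of the erythemal action spectrum EE(lambda) and the solar
#' intensity spectrum I(lambda) at the seven 5 nm grid points of the UV-B
#' band, normalized so the weights sum to one (within 0.001), together with
#' the correction factor CF = 10. These are the standard tabulated
#' constants of the spectrophotometric (Mansur) SPF method.
#'
#' @return A data.frame with columns `wavelength_nm` and `weight`, with the
#'   correction factor in attribute `cf`.
#' @examples
#' sum(erythemal_weights()$weight)  # ~1.0002
#' @export
erythemal_weights <- function() {
  w <- data.frame(
    wavelength_nm = c(290, 295, 300, 305, 310, 315, 320),
    weight = c(0.0150, 0.0817, 0.2874, 0.3278, 0.1864, 0.0839, 0.0180)
  )
  stopifnot(abs(sum(w$weight) - 1) < 0.001)
  attr(w, "cf") <- 10
  w
}

# Clip baseline artifacts: metrics integrate nonnegative absorbance.
clip_negative <- function(a, what) {
  if (any(a < 0)) {
    warning(sprintf("%s: %d negative absorbance value(s) clipped to 0",
                    what, sum(a < 0)), call. = FALSE)
    a[a < 0] <- 0
  }
  a
}

#' In vitro sun protection factor (SPFi)
#'
#' Erythemal-weighted absorbance sum over the UV-B band:
#' `SPFi = CF * sum_{290..320 nm, step 5} EE(l) I(l) A(l)`, with
#' correction factor CF = 10 and absorbance taken at the seven 5 nm grid
#' points exactly (linear interpolation if the raw grid lacks them).
#'
#' @param spec An [absorbance_spectrum()] covering at least 290-320 nm.
#' @param weights Weight table from [erythemal_weights()] (or a compatible
#'   data.frame with attribute `cf`).
#' @return SPFi, a nonnegative dimensionless scalar (for nonnegative
#'   spectra).
#' @examples
#' s <- absorbance_spectrum(290:400, rep(1, 111))
#' spfi(s)  # 10.002
#' @export
spfi <- function(spec, weights = erythemal_weights()) {
  stopifnot(inherits(spec, "absorbance_spectrum"))
  check_coverage(spec, min(weights$wavelength_nm), max(weights$wavelength_nm))
  a <- stats::approx(spec$wavelength_nm, spec$absorbance_au,
                     xout = weights$wavelength_nm)$y
  a <- clip_negative(a, "spfi")
  cf <- attr(weights, "cf")
  if (is.null(cf)) cf <- 10
  cf * sum(weights$weight * a)
}

# Trapezoid integral of y over x (x ascending).
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)

#' Critical wavelength
#'
#' The smallest wavelength `lambda_c` at which the cumulative absorbance
#' integral from 290 nm reaches 90\% of the total 290-400 nm integral.
#' Computed by composite trapezoid on the spectrum's grid with linear
#' interpolation of the cumulative integral within the bracketing segment.
#' A value above 370 nm supports a broad-spectrum (UV-A protection) claim.
#'
#' @param spec An [absorbance_spectrum()] covering 290-400 nm.
#' @param fraction Cumulative fraction defining the metric (default 0.9).
#' @return A list with `lambda_c` (nm, 0.1 nm resolution) and `lambda_c_nm`
#'   (rounded to the nearest integer nm, the conventional reporting form).
#' @examples
#' s <- absorbance_spectrum(290:400, rep(1, 111))
#' critical_wavelength(s)$lambda_c  # 389
#' @export
critical_wavelength <- function(spec, fraction = 0.9) {
  stopifnot(inherits(spec, "absorbance_spectrum"))
  check_coverage(spec, 290, 400)
  keep <- spec$wavelength_nm >= 290 & spec$wavelength_nm <= 400
  w <- spec$wavelength_nm[keep]
  a <- clip_negative(spec$absorbance_au[keep], "critical_wavelength")
  seg <- diff(w) * (utils::head(a, -1L) + utils::tail(a, -1L)) / 2
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0)
    stop("critical wavelength undefined: spectrum integrates to zero", call. = FALSE)
  target <- fraction * total
  i <- which(cum >= target)[1L]
  lc <- if (i == 1L) w[1L] else {
    # linear interpolation of the cumulative integral in the bracket
    w[i - 1L] + (target - cum[i - 1L]) / (cum[i] - cum[i - 1L]) * (w[i] - w[i - 1L])
  }
  list(lambda_c = round(lc, 1L), lambda_c_nm = as.integer(round(lc)))
}

#' UVA/UVB absorbance ratio
#'
#' Trapezoidal integral of absorbance over the UV-A band (320-400 nm)
#' divided by the integral over the UV-B band (290-320 nm). The basis of
#' the Boots star rating.
#'
#' @param spec An [absorbance_spectrum()] covering 290-400 nm.
#' @return Dimensionless nonnegative ratio.
#' @export
uva_uvb_ratio <- function(spec) {
  stopifnot(inherits(spec, "absorbance_spectrum"))
  check_coverage(spec, 290, 400)
  w <- spec$wavelength_nm
  a <- clip_negative(spec$absorbance_au, "uva_uvb_ratio")
  band_int <- function(lo, hi) {
    grid <- sort(unique(c(lo, hi, w[w >= lo & w <= hi])))
    trapz(grid, stats::approx(w, a, xout = grid)$y)
  }
  uvb <- band_int(290, 320)
  if (uvb <= 0)
    stop("UVA/UVB ratio undefined: UV-B integral is zero", call. = FALSE)
  band_int(320, 400) / uvb
}

#' Boots star rating from the UVA/UVB ratio
#'
#' Classifies the mean UVA/UVB ratio into the Boots star bands:
#' below 0.6 no claim (0 stars), 0.6-0.8 three stars, 0.8-0.9 four stars,
#' 0.9 and above five stars. Lower bands of older Boots schemes (1-2
#' stars) are deliberately collapsed into "no claim".
#'
#' @param ratio Nonnegative UVA/UVB ratio.
#' @param boundaries Ascending band boundaries, defaults `c(0.6, 0.8, 0.9)`.
#' @return Integer star rating in `{0, 3, 4, 5}`.
#' @export
star_rating <- function(ratio, boundaries = c(0.6, 0.8, 0.9)) {
  if (!is.finite(ratio) || ratio < 0)
    stop("star_rating: ratio must be a nonnegative number", call. = FALSE)
  stopifnot(length(boundaries) == 3L, !is.unsorted(boundaries))
  stars <- c(0L, 3L, 4L, 5L)
  stars[findInterval(ratio, boundaries) + 1L]
}

#' Broad-spectrum (UV-A protection) claim
#'
#' TRUE when the critical wavelength strictly exceeds the configured cutoff
#' (default 370 nm) and the UVA/UVB ratio meets the configured cutoff
#' (default 0.7, inclusive).
#'
#' @param lambda_c Critical wavelength in nm.
#' @param ratio UVA/UVB ratio.
#' @param config A [run_config()].
#' @return Logical scalar.
#' @export
broad_spectrum_claim <- function(lambda_c, ratio, config = run_config()) {
  stopifnot(is.finite(lambda_c), is.finite(ratio))
  lambda_c > config$lambda_c_cutoff_nm && ratio >= config$uva_uvb_cutoff
}

#' All UV-absorbing metrics for one spectrum
#'
#' Convenience wrapper resampling to the configured grid and computing
#' SPFi, critical wavelength, UVA/UVB ratio, star rating and the
#' broad-spectrum flag.
#'
#' @param spec An [absorbance_spectrum()] covering 290-400 nm.
#' @param config A [run_config()].
#' @return One-row data.frame with columns `sample_id`, `spfi`,
#'   `lambda_c_nm`, `uva_uvb_ratio`, `stars`, `broad_spectrum`.
#' @export
uv_metrics <- function(spec, config = run_config()) {
  rs <- resample_spectrum(spec, step = config$wavelength_step_nm,
                          from = config$full_band[1L], to = config$full_band[2L])
  lc <- critical_wavelength(rs)
  ratio <- uva_uvb_ratio(rs)
  data.frame(
    sample_id = attr(spec, "sample_id"),
    spfi = spfi(rs),
    lambda_c_nm = lc$lambda_c,
    uva_uvb_ratio = ratio,
    stars = star_rating(ratio),
    broad_spectrum = broad_spectrum_claim(lc$lambda_c, ratio, config),
    stringsAsFactors = FALSE
  )
}
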