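#' Absorbance spectrum container
#'
#' A UV absorbance spectrum on the 290-400 nm band: the substrate for the
#' in vitro SPF, critical-wavelength and UVA/UVB-ratio metrics.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   ascending after construction (descending input is sorted with a
#'   warning).
#' @param absorbance Numeric vector of absorbance values (AU), same length.
#' @param sample_id Sample label.
#' @param concentration Optional test concentration (mg/mL) recorded for
#'   provenance.
#'
#' @details Negative absorbance values (baseline artifacts) are preserved
#' in the container but flagged via the `has_negative` attribute; metric
#' functions clip them to zero before integrating.
#'
#' @return Object of class `absorbance_spectrum`: a data.frame with columns
#'   `wavelength_nm` and `absorbance_au`.
#' @export
absorbance_spectrum <- function(wavelengths, absorbance,
                                sample_id = "sample", concentration = NA_real_) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.numeric(absorbance)
  if (length(wavelengths) != length(absorbance))
    stop("wavelengths and absorbance must have the same length", call. = FALSE)
  if (length(wavelengths) < 2L)
    stop("a spectrum needs at least two points", call. = FALSE)
  if (anyNA(wavelengths) || anyNA(absorbance))
    stop("spectrum contains NA values", call. = FALSE)
  d <- diff(wavelengths)
  if (all(d < 0)) {
    warning("wavelengths were descending; sorted ascending", call. = FALSE)
    o <- order(wavelengths)
    wavelengths <- wavelengths[o]
    absorbance <- absorbance[o]
  } else if (any(d <= 0)) {
    stop("wavelengths must be strictly monotone", call. = FALSE)
  }
  s <- data.frame(wavelength_nm = wavelengths, absorbance_au = absorbance)
  attr(s, "sample_id") <- as.character(sample_id)
  attr(s, "concentration") <- as.numeric(concentration)
  attr(s, "has_negative") <- any(absorbance < 0)
  class(s) <- c("absorbance_spectrum", "data.frame")
  s
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  rng <- range(x$wavelength_nm)
  cat(sprintf("<absorbance_spectrum> %s: %d points, %.1f-%.1f nm, max A = %.3f\n",
              attr(x, "sample_id"), nrow(x), rng[1L], rng[2L],
              max(x$absorbance_au)))
  invisible(x)
}

# Assert the spectrum covers [lo, hi]; raise a coverage error naming the gap.
check_coverage <- function(spec, lo, hi) {
  w <- spec$wavelength_nm
  if (min(w) > lo || max(w) < hi) {
    gaps <- character(0L)
    if (min(w) > lo) gaps <- c(gaps, sprintf("%g-%g missing", lo, min(w) - 1))
    if (max(w) < hi) gaps <- c(gaps, sprintf("%g-%g missing", max(w) + 1, hi))
    stop(sprintf("spectrum does not cover [%g, %g] nm: %s",
                 lo, hi, paste(gaps, collapse = "; ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Resample a spectrum onto a uniform wavelength grid
#'
#' Linear interpolation onto `seq(from, to, by = step)`. Used to put raw
#' instrument grids onto the configured analysis grid before metric
#' computation.
#'
#' @param spec An [absorbance_spectrum()].
#' @param step Grid step in nm.
#' @param from,to Band limits in nm (defaults: the 290-400 nm UV band).
#' @return A new `absorbance_spectrum` on the uniform grid.
#' @export
resample_spectrum <- function(spec, step = 1, from = 290, to = 400) {
  stopifnot(inherits(spec, "absorbance_spectrum"))
  check_coverage(spec, from, to)
  grid <- seq(from, to, by = step)
  a <- stats::approx(spec$wavelength_nm, spec$absorbance_au, xout = grid)$y
  absorbance_spectrum(grid, a, sample_id = attr(spec, "sample_id"),
                      concentration = attr(spec, "concentration"))
}

#' Read an absorbance spectrum from a two-column CSV
#'
#' Expects a header and two numeric columns (wavelength nm, absorbance AU)
#' or named columns selected through `dialect`. The spectrum is restricted
#' to the 290-400 nm band and must cover it fully.
#'
#' @param path CSV file path.
#' @param dialect Named list mapping `wavelength` and `absorbance` to column
#'   names or indices (default: first two columns).
#' @param sample_id Sample label; defaults to the file base name.
#' @param band Restriction band in nm.
#' @return An [absorbance_spectrum()].
#' @export
read_spectrum <- function(path, dialect = list(wavelength = 1L, absorbance = 2L),
                          sample_id = NULL, band = c(290, 400)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  pick <- function(key) {
    col <- dialect[[key]]
    v <- if (is.character(col)) df[[col]] else df[[as.integer(col)]]
    if (is.null(v)) stop("column for ", key, " not found in ", path, call. = FALSE)
    as.numeric(v)
  }
  w <- pick("wavelength"); a <- pick("absorbance")
  if (anyNA(w) || anyNA(a))
    stop("non-numeric values in spectrum file ", path, call. = FALSE)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  s <- absorbance_spectrum(w, a, sample_id = sample_id)
  check_coverage(s, band[1L], band[2L])
  keep <- s$wavelength_nm >= band[1L] & s$wavelength_nm <= band[2L]
  absorbance_spectrum(s$wavelength_nm[keep], s$absorbance_au[keep],
                      sample_id = sample_id)
}

#' Write an absorbance spectrum to CSV
#'
#' Round-trips with [read_spectrum()] to at least six decimals.
#'
#' @param spec An [absorbance_spectrum()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "absorbance_spectrum"))
  utils::write.csv(
    data.frame(wavelength_nm = spec$wavelength_nm,
               absorbance_au = spec$absorbance_au),
    path, row.names = FALSE)
  invisible(path)
}
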