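#' Cell viability from treated and untreated absorbances
#'
#' MTT formazan absorbance is proportional to viable cells, so
#' `viability(%) = 100 * mean(A_T) / mean(A_U)`. Values above 100
#' (proliferation) are permitted and flagged. The statistic is invariant
#' to a common rescaling of absorbance units.
#'
#' @param a_t Treated-well absorbance replicates.
#' @param a_u Untreated-control absorbance replicates.
#' @return List with `viability_pct`, `sd_pct`, `n`, `above_100`.
#' @examples
#' viability(c(0.60, 0.62), c(0.80, 0.82))$viability_pct
#' @export
viability <- function(a_t, a_u) {
  a_t <- as.numeric(a_t); a_u <- as.numeric(a_u)
  if (length(a_t) < 1L || length(a_u) < 1L || anyNA(a_t) || anyNA(a_u))
    stop("treated and untreated replicates must be nonempty and NA-free", call. = FALSE)
  au <- mean(a_u)
  if (au <= 0)
    stop("assay error: untreated mean absorbance must be positive", call. = FALSE)
  per_rep <- 100 * a_t / au
  list(viability_pct = mean(per_rep),
       sd_pct = if (length(a_t) > 1L) stats::sd(per_rep) else NA_real_,
       n = length(a_t),
       above_100 = mean(per_rep) > 100)
}

#' Dose-response series container
#'
#' @param concentrations Doses in ug/mL, ascending (sorted if not).
#' @param viability Viability (\%) at each dose.
#' @param sample_id Sample label.
#' @return Object of class `dose_response` (a data.frame).
#' @export
dose_response <- function(concentrations, viability, sample_id = "sample") {
  x <- as.numeric(concentrations); y <- as.numeric(viability)
  if (length(x) != length(y) || anyNA(x) || anyNA(y) || any(x <= 0))
    stop("dose_response: doses must be positive and viability finite", call. = FALSE)
  o <- order(x)
  d <- data.frame(concentration = x[o], viability_pct = y[o])
  attr(d, "sample_id") <- sample_id
  class(d) <- c("dose_response", "data.frame")
  d
}

# 4PL on log10 dose: v(c) = bottom + (top - bottom) / (1 + (c/ec50)^hill)
four_pl <- function(conc, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (conc / ec50)^hill)
}

#' Four-parameter logistic IC50 fit
#'
#' Fits `v(c) = bottom + (top - bottom) / (1 + (c/ec50)^hill)` by least
#' squares (free asymptotes, initialized at the min/max observed viability;
#' ec50 initialized at the geometric mean of the doses). The reported IC50
#' is the dose at which the fitted curve crosses absolute 50\% viability
#' (not the curve's inflection). When no observed mean viability falls at
#' or below 50\%, the result is right-censored at the top test dose; when
#' the optimizer fails, a log-linear interpolation between the doses
#' bracketing 50\% is used instead and tagged as such.
#'
#' @param series A [dose_response()] with at least 4 doses (for the 4PL
#'   route).
#' @return List with `ic50` (ug/mL, `NA` when censored), `censored`,
#'   `censor_bound` ("IC50 > c_max" when censored), `method` (`"4pl"` or
#'   `"interpolation"`), and the fitted `bottom`, `top`, `hill`, `ec50`
#'   when available.
#' @export
fit_ic50 <- function(series) {
  stopifnot(inherits(series, "dose_response"))
  conc <- series$concentration
  v <- series$viability_pct
  if (min(v) > 50) {
    return(list(ic50 = NA_real_, censored = TRUE,
                censor_bound = sprintf("IC50 > %g", max(conc)),
                method = "censored",
                bottom = NA_real_, top = NA_real_, hill = NA_real_,
                ec50 = NA_real_))
  }
  fit <- NULL
  if (length(conc) >= 4L) {
    start <- list(bottom = max(min(v), 0), top = max(v),
                  ec50 = exp(mean(log(conc))), hill = 1)
    fit <- tryCatch(
      stats::nls(v ~ four_pl(conc, bottom, top, ec50, hill),
                 start = start, algorithm = "port",
                 lower = c(bottom = -20, top = 10, ec50 = min(conc) / 100, hill = 0.1),
                 upper = c(bottom = 60, top = 200, ec50 = max(conc) * 100, hill = 10),
                 control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    p <- as.list(stats::coef(fit))
    if (p$top > 50 && p$bottom < 50) {
      ic50 <- p$ec50 * ((p$top - 50) / (50 - p$bottom))^(1 / p$hill)
      return(list(ic50 = ic50, censored = FALSE, censor_bound = NA_character_,
                  method = "4pl", bottom = p$bottom, top = p$top,
                  hill = p$hill, ec50 = p$ec50))
    }
  }
  # fallback: log-linear interpolation between the doses bracketing 50%
  below <- which(v <= 50)
  i <- below[1L]
  if (i == 1L) {
    ic50 <- conc[1L]
  } else {
    f <- (v[i - 1L] - 50) / (v[i - 1L] - v[i])
    ic50 <- 10^(log10(conc[i - 1L]) + f * (log10(conc[i]) - log10(conc[i - 1L])))
  }
  list(ic50 = ic50, censored = FALSE, censor_bound = NA_character_,
       method = "interpolation", bottom = NA_real_, top = NA_real_,
       hill = NA_real_, ec50 = NA_real_)
}

#' Convert a medium concentration into an areal dose on the cell monolayer
#'
#' `dose (ug/cm^2) = concentration (ug/mL) * volume (mL) / growth area
#' (cm^2)`. Defaults are standard 96-well geometry (200 uL in 0.32 cm^2),
#' under which an IC50 of 75.93 ug/mL corresponds to 47.46 ug/cm^2 --
#' directly comparable with recommended sunscreen application doses
#' (2000 ug/cm^2).
#'
#' @param concentration ug/mL.
#' @param volume_ul Well volume in uL (default 200).
#' @param area_cm2 Well growth area in cm^2 (default 0.32).
#' @return Areal dose in ug/cm^2.
#' @examples
#' areal_dose(75.93)  # 47.46
#' @export
areal_dose <- function(concentration, volume_ul = 200, area_cm2 = 0.32) {
  if (!is.finite(volume_ul) || volume_ul <= 0 || !is.finite(area_cm2) || area_cm2 <= 0)
    stop("areal_dose: volume and area must be positive", call. = FALSE)
  if (any(!is.finite(concentration) | concentration < 0))
    stop("areal_dose: concentration must be nonnegative", call. = FALSE)
  concentration * (volume_ul / 1000) / area_cm2
}

#' Non-toxicity flag at the top test dose
#'
#' TRUE when viability at the highest tested dose strictly exceeds the
#' configured cutoff (default 75\%).
#'
#' @param series A [dose_response()] containing the top test dose.
#' @param config A [run_config()].
#' @return Logical scalar.
#' @export
nontoxic_flag <- function(series, config = run_config()) {
  stopifnot(inherits(series, "dose_response"))
  v_top <- series$viability_pct[which.max(series$concentration)]
  v_top > config$viability_cutoff_pct
}
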