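# Run `expr` with a private RNG state seeded at `seed`, restoring the
# caller's state afterwards. Generators take explicit seeds; no global
# random state leaks.
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Synthetic multi-band absorbance spectrum
#'
#' Emulates a recorded UV absorbance spectrum as a sum of Gaussian bands
#' plus a flat baseline and additive Gaussian plate noise, clipped at 0:
#' `A(l) = max(0, baseline + sum_k peak_k exp(-(l - center_k)^2 / (2
#' sigma_k^2)) + N(0, noise_sd))`. Gaussian bands keep closed-form
#' integrals available for independent oracles.
#'
#' @param bands data.frame with columns `center` (nm, within 250-450),
#'   `width` (Gaussian sigma, nm, > 0), `peak` (AU).
#' @param baseline Baseline absorbance (AU).
#' @param noise_sd Additive noise SD (AU, >= 0).
#' @param step Wavelength grid step (nm).
#' @param seed Integer seed (reproducible; callers' RNG state untouched).
#' @param sample_id Sample label.
#' @param band Wavelength range to generate, default `c(290, 400)`.
#' @return An [absorbance_spectrum()].
#' @examples
#' s <- make_spectrum(data.frame(center = 305, width = 10, peak = 1), seed = 1)
#' @export
make_spectrum <- function(bands, baseline = 0, noise_sd = 0, step = 1,
                          seed = 1L, sample_id = "synthetic",
                          band = c(290, 400)) {
  stopifnot(is.data.frame(bands),
            all(c("center", "width", "peak") %in% names(bands)))
  if (any(bands$width <= 0) || any(bands$center < 250 | bands$center > 450) ||
      noise_sd < 0)
    stop("make_spectrum: invalid band model", call. = FALSE)
  grid <- seq(band[1L], band[2L], by = step)
  a <- rep(baseline, length(grid))
  for (k in seq_len(nrow(bands)))
    a <- a + bands$peak[k] * exp(-(grid - bands$center[k])^2 / (2 * bands$width[k]^2))
  if (noise_sd > 0)
    a <- a + with_private_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  absorbance_spectrum(grid, pmax(a, 0), sample_id = sample_id)
}

#' Design a synthetic screening panel with known ground truth
#'
#' Emulates a screen of morphologically distinct isolates: each isolate
#' gets true DPPH/ABTS scavenging capacities, a spectral band model, and a
#' true 4PL viability curve, arranged so that exactly `n_pass` isolates
#' satisfy every selection filter with a comfortable margin while the rest
#' fail at least one. Failure modes rotate between low scavenging (one or
#' both assays), a weak UV-B-only spectrum (low SPFi), and a missing UV-A
#' band (low critical wavelength / ratio).
#'
#' @param n_isolates Panel size (default 35, a realistic screen).
#' @param n_pass Number of isolates designed to pass (default 10).
#' @param seed Integer seed.
#' @return Object of class `panel_design`: data.frame with the truth per
#'   isolate plus a `bands` list-column, and attributes `pass_set`,
#'   `seed`.
#' @export
make_panel_design <- function(n_isolates = 35L, n_pass = 10L, seed = 1L) {
  stopifnot(n_pass <= n_isolates, n_isolates >= 1L)
  with_private_seed(seed, {
    id <- sprintf("ISO%02d", seq_len(n_isolates))
    pass <- seq_len(n_pass)  # first n_pass isolates pass; labels are arbitrary
    d <- data.frame(isolate_id = id, pass = seq_len(n_isolates) %in% pass,
                    stringsAsFactors = FALSE)
    d$true_rsc_dpph <- ifelse(d$pass, stats::runif(n_isolates, 58, 80),
                              stats::runif(n_isolates, 20, 42))
    d$true_rsc_abts <- ifelse(d$pass, stats::runif(n_isolates, 58, 80),
                              stats::runif(n_isolates, 20, 42))
    # failure modes for the non-pass isolates: 1 = low RSC only (UV fine),
    # 2 = weak UV-B-only spectrum, 3 = low RSC + no UV-A band
    mode <- rep(0L, n_isolates)
    mode[!d$pass] <- rep_len(1:3, n_isolates - n_pass)
    bands <- vector("list", n_isolates)
    for (i in seq_len(n_isolates)) {
      uvb_peak <- stats::runif(1L, 0.5, 0.9)
      uva_peak <- stats::runif(1L, 1.0, 1.6)
      bands[[i]] <- switch(
        as.character(mode[i]),
        "0" = ,  # pass: strong UV-B + strong UV-A band
        "1" = data.frame(center = c(305, 370), width = c(12, 20),
                         peak = c(uvb_peak, uva_peak)),
        "2" = data.frame(center = 305, width = 8, peak = 0.05),
        "3" = data.frame(center = 305, width = 10, peak = uvb_peak))
    }
    d$bands <- I(bands)
    # true 4PL viability: pass isolates essentially non-toxic
    d$true_viab_top <- ifelse(d$pass, stats::runif(n_isolates, 82, 98),
                              stats::runif(n_isolates, 60, 95))
    attr(d, "pass_set") <- id[pass]
    attr(d, "seed") <- as.integer(seed)
    class(d) <- c("panel_design", "data.frame")
    d
  })
}

#' Simulate assay plates for a panel design
#'
#' Radical-assay plates: blanks drawn near 0.70 AU (the adjusted radical
#' working solution), triplicate sample absorbances back-computed from the
#' true scavenging capacity via the assay equation, with additive Gaussian
#' plate noise. A viability plate holds untreated controls and triplicate
#' treated wells at the top test dose computed from the design's true
#' viability.
#'
#' @param design A [make_panel_design()] output.
#' @param noise_sd Absorbance noise SD (AU, default 0.005).
#' @param n_rep Replicates per group (default 3).
#' @param seed Integer seed.
#' @param top_dose Top test dose recorded on the viability plate (ug/mL).
#' @return Named list of `assay_plate`s: `DPPH`, `ABTS`, `MTT`.
#' @export
make_plates <- function(design, noise_sd = 0.005, n_rep = 3L, seed = 1L,
                        top_dose = 500) {
  stopifnot(inherits(design, "panel_design"))
  with_private_seed(seed, {
    mk_radical <- function(true_rsc) {
      blank <- stats::rnorm(n_rep, 0.70, 0.02 / 2)
      samp <- lapply(stats::setNames(seq_len(nrow(design)), design$isolate_id),
                     function(i) {
                       a_true <- mean(blank) * (1 - true_rsc[i] / 100)
                       pmax(a_true + stats::rnorm(n_rep, 0, noise_sd), 0)
                     })
      structure(list(assay = NULL, blank_abs = blank, sample_abs = samp),
                class = "assay_plate")
    }
    dpph <- mk_radical(design$true_rsc_dpph)
    dpph$assay <- "DPPH"
    abts <- mk_radical(design$true_rsc_abts)
    abts$assay <- "ABTS"
    untreated <- stats::rnorm(n_rep, 0.80, noise_sd)
    treated <- lapply(stats::setNames(seq_len(nrow(design)),
                                      paste0(design$isolate_id, "@", top_dose)),
                      function(i) {
                        a_true <- mean(untreated) * design$true_viab_top[i] / 100
                        pmax(a_true + stats::rnorm(n_rep, 0, noise_sd), 0)
                      })
    mtt <- structure(list(assay = "MTT", untreated_abs = untreated,
                          treated_abs = treated,
                          treated_key = data.frame(
                            sample_id = design$isolate_id,
                            concentration = top_dose,
                            key = paste0(design$isolate_id, "@", top_dose))),
                     class = "assay_plate")
    list(DPPH = dpph, ABTS = abts, MTT = mtt)
  })
}

#' Simulate a dose-response viability series from a true 4PL curve
#'
#' @param ic50 True IC50 (ug/mL) at absolute 50\% viability (with
#'   `bottom = 0`, `top = 100` this equals the 4PL midpoint).
#' @param doses Dose grid (ug/mL); default the 8-point series
#'   3.13-400 ug/mL used for a reference UV filter.
#' @param hill Hill slope (default 1.5).
#' @param bottom,top Asymptotes (\%).
#' @param noise_sd Viability noise SD in percentage points (default 2).
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return A [dose_response()].
#' @export
make_dose_response <- function(ic50, doses = c(3.13, 6.25, 12.5, 25, 50, 100,
                                               200, 400),
                               hill = 1.5, bottom = 0, top = 100,
                               noise_sd = 2, seed = 1L, sample_id = "synthetic") {
  v_true <- four_pl(doses, bottom, top, ic50, hill)
  v <- if (noise_sd > 0)
    v_true + with_private_seed(seed, stats::rnorm(length(doses), 0, noise_sd))
  else v_true
  dose_response(doses, v, sample_id = sample_id)
}

#' Simulate cross-extract LC-MS feature tables with planted truth
#'
#' Builds one feature table per extract from planted molecular formulas
#' and adducts: observed m/z is the theoretical adduct m/z perturbed by a
#' uniform mass error (`+/- jitter_ppm`), retention times are uniform on
#' 2-26 min, and `shared` features (same compound, same RT) are planted
#' across the named pairs of extracts.
#'
#' @param extract_ids Extract labels.
#' @param n_unique Unique (unshared) features per extract.
#' @param shared Named list: each element `c("A", "B")` plants
#'   `n_shared` common features between those two extracts.
#' @param n_shared Number of planted shared features per pair (default 9).
#' @param jitter_ppm Half-width of the uniform ppm mass error (default 5).
#' @param seed Integer seed.
#' @return Named list of [feature_table()]s; the planted shared features
#'   carry ids `SHARED<k>_<pairname>` in every member extract.
#' @export
make_feature_tables <- function(extract_ids, n_unique = 20L,
                                shared = list(), n_shared = 9L,
                                jitter_ppm = 5, seed = 1L) {
  with_private_seed(seed, {
    # formula pool: plausible CHNO compositions, well separated in mass
    pool <- expand.grid(C = seq(15, 44, by = 1), N = 0:4)
    pool$H <- pool$C + 10 + 2 * pool$N
    pool$O <- 2 + (pool$C %% 7)
    pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
    fml <- sprintf("C%dH%dN%dO%d", pool$C, pool$H, pool$N, pool$O)
    fml <- gsub("N0", "", fml)
    k <- 0L
    next_formula <- function() { k <<- k + 1L; fml[k] }
    adducts <- names(ADDUCT_SHIFTS)
    gen_row <- function(id, formula, rt) {
      ad <- sample(adducts, 1L)
      mz <- adduct_mz(formula, ad, digits = NA)
      mz_obs <- mz * (1 + stats::runif(1L, -jitter_ppm, jitter_ppm) / 1e6)
      data.frame(feature_id = id, rt_min = rt, mz_observed = mz_obs,
                 formula = formula, adduct = ad, stringsAsFactors = FALSE)
    }
    tabs <- lapply(stats::setNames(extract_ids, extract_ids), function(ex) {
      do.call(rbind, lapply(seq_len(n_unique), function(j)
        gen_row(sprintf("%s_U%02d", ex, j), next_formula(),
                stats::runif(1L, 2, 26))))
    })
    for (nm in names(shared)) {
      pair <- shared[[nm]]
      for (j in seq_len(n_shared)) {
        formula <- next_formula()
        rt <- stats::runif(1L, 2, 26)
        ad <- sample(adducts, 1L)
        mz <- adduct_mz(formula, ad, digits = NA)
        for (ex in pair) {
          mz_obs <- mz * (1 + stats::runif(1L, -jitter_ppm, jitter_ppm) / 1e6)
          tabs[[ex]] <- rbind(tabs[[ex]], data.frame(
            feature_id = sprintf("SHARED%02d_%s", j, nm), rt_min = rt,
            mz_observed = mz_obs, formula = formula, adduct = ad,
            stringsAsFactors = FALSE))
        }
      }
    }
    lapply(stats::setNames(names(tabs), names(tabs)), function(ex) {
      t <- tabs[[ex]]
      feature_table(ex, t$feature_id, t$rt_min, t$mz_observed, t$formula,
                    t$adduct)
    })
  })
}

#' Run the full screening pipeline on simulated panel data
#'
#' Generates spectra and plates from a [make_panel_design()], recovers the
#' per-isolate metrics through the measurement pipeline (not the truth),
#' and applies [screen_panel()].
#'
#' @param design A [make_panel_design()] output.
#' @param config A [run_config()].
#' @param noise_sd Plate/spectrum noise SD (AU).
#' @param seed Integer seed.
#' @return Output of [screen_panel()] plus element `metrics` (the
#'   recovered per-isolate record table).
#' @export
simulate_screen <- function(design, config = run_config(), noise_sd = 0.005,
                            seed = 1L) {
  stopifnot(inherits(design, "panel_design"))
  plates <- make_plates(design, noise_sd = noise_sd, seed = seed + 1L)
  records <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    id <- design$isolate_id[i]
    spec <- make_spectrum(design$bands[[i]], noise_sd = noise_sd,
                          step = config$wavelength_step_nm,
                          seed = seed + 100L + i, sample_id = id)
    uv <- uv_metrics(spec, config)
    dpph <- radical_scavenging(plates$DPPH$blank_abs, plates$DPPH$sample_abs[[id]])
    abts <- radical_scavenging(plates$ABTS$blank_abs, plates$ABTS$sample_abs[[id]])
    key <- plates$MTT$treated_key$key[plates$MTT$treated_key$sample_id == id]
    viab <- viability(plates$MTT$treated_abs[[key]], plates$MTT$untreated_abs)
    data.frame(isolate_id = id, rsc_dpph = dpph$rsc_pct, rsc_abts = abts$rsc_pct,
               spfi = uv$spfi, lambda_c_nm = uv$lambda_c_nm,
               uva_uvb_ratio = uv$uva_uvb_ratio,
               viability_top_dose = viab$viability_pct,
               stringsAsFactors = FALSE)
  }))
  out <- screen_panel(records, config)
  out$metrics <- records
  out
}
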