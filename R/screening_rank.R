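#' Apply the photoprotection selection filters to a screening panel
#'
#' Keeps isolates whose extracts pass all of: DPPH scavenging above the
#' cutoff, ABTS scavenging above the cutoff, SPFi above the cutoff,
#' critical wavelength strictly above the cutoff, and UVA/UVB ratio at or
#' above the cutoff (defaults 50\%, 50\%, 2, 370 nm, 0.7). Records with
#' any missing metric are excluded with status `"incomplete"` rather than
#' silently dropped. A per-record, per-criterion audit trail is attached.
#'
#' @param records data.frame with columns `isolate_id`, `rsc_dpph`,
#'   `rsc_abts`, `spfi`, `lambda_c_nm`, `uva_uvb_ratio`.
#' @param config A [run_config()].
#' @return The input with added logical columns `pass_dpph`, `pass_abts`,
#'   `pass_spfi`, `pass_lambda_c`, `pass_ratio`, a `status` column
#'   (`"selected"`, `"rejected"`, `"incomplete"`) and a `selected` flag;
#'   the long-format audit trail is in `attr(, "audit")`.
#' @export
select_candidates <- function(records, config = run_config()) {
  need <- c("isolate_id", "rsc_dpph", "rsc_abts", "spfi", "lambda_c_nm",
            "uva_uvb_ratio")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  crit <- list(
    dpph = list(value = records$rsc_dpph, thr = config$rsc_cutoff_pct, op = ">"),
    abts = list(value = records$rsc_abts, thr = config$rsc_cutoff_pct, op = ">"),
    spfi = list(value = records$spfi, thr = config$spfi_cutoff, op = ">"),
    lambda_c = list(value = records$lambda_c_nm, thr = config$lambda_c_cutoff_nm, op = ">"),
    ratio = list(value = records$uva_uvb_ratio, thr = config$uva_uvb_cutoff, op = ">=")
  )
  audit <- do.call(rbind, lapply(names(crit), function(nm) {
    cc <- crit[[nm]]
    pass <- if (cc$op == ">") cc$value > cc$thr else cc$value >= cc$thr
    data.frame(isolate_id = records$isolate_id, criterion = nm,
               value = cc$value, threshold = cc$thr, op = cc$op,
               pass = pass, stringsAsFactors = FALSE)
  }))
  for (nm in names(crit)) {
    cc <- crit[[nm]]
    records[[paste0("pass_", nm)]] <-
      if (cc$op == ">") cc$value > cc$thr else cc$value >= cc$thr
  }
  pcols <- paste0("pass_", names(crit))
  complete <- stats::complete.cases(records[need])
  allpass <- rowSums(records[pcols], na.rm = FALSE) == length(pcols)
  records$status <- ifelse(!complete, "incomplete",
                           ifelse(allpass, "selected", "rejected"))
  records$selected <- records$status == "selected"
  attr(records, "audit") <- audit
  records
}

#' Radar triangle-area composite photoprotection score
#'
#' The area of the triangle whose vertices lie at distances `(v1, v2, v3)`
#' along three radar axes 120 degrees apart:
#' `(sqrt(3)/4) * (v1 v2 + v2 v3 + v3 v1)`. With exactly three axes the
#' area does not depend on axis order, so the score is symmetric in its
#' arguments and homogeneous of degree two. The three axes are SPFi
#' expressed as a percentage of the reference UV filter, DPPH scavenging
#' (\%), and ABTS scavenging (\%); all must be on the same 0-100 scale and
#' nonnegative (negative scavenging must be floored to 0 by the caller and
#' flagged).
#'
#' @param spfi_pct SPFi as \% of the reference filter's SPFi.
#' @param rsc_dpph,rsc_abts Radical-scavenging capacities (\%).
#' @return Triangle area (score), nonnegative.
#' @examples
#' triangle_score(50, 60, 70)  # 4633.2
#' @export
triangle_score <- function(spfi_pct, rsc_dpph, rsc_abts) {
  v <- c(spfi_pct, rsc_dpph, rsc_abts)
  if (any(!is.finite(v)) || any(v < 0))
    stop("triangle_score: axis values must be finite and nonnegative",
         call. = FALSE)
  sqrt(3) / 4 * (spfi_pct * rsc_dpph + rsc_dpph * rsc_abts + rsc_abts * spfi_pct)
}

#' Rank screening records by composite score
#'
#' Descending by `score`; exact ties broken by `spfi_pct` (descending)
#' then `isolate_id` (lexicographic), so re-running on shuffled input
#' yields identical output.
#'
#' @param records data.frame with `isolate_id`, `score`, and optionally
#'   `spfi_pct`.
#' @return The records sorted, with a `rank` column (1 = best).
#' @export
rank_records <- function(records) {
  stopifnot(all(c("isolate_id", "score") %in% names(records)))
  spfi_pct <- if ("spfi_pct" %in% names(records)) records$spfi_pct else
    rep(0, nrow(records))
  o <- order(-records$score, -spfi_pct, records$isolate_id)
  out <- records[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r with the two-sided p-value from the t distribution on
#' n - 2 degrees of freedom (`t = r sqrt((n-2)/(1-r^2))`). Used to relate
#' total phenolic/flavonoid contents to radical-scavenging capacity. No
#' multiplicity adjustment is applied by default.
#'
#' @param x,y Numeric vectors, length >= 3, finite.
#' @param bonferroni_m Optional number of tests for a Bonferroni-adjusted
#'   p (default 1, i.e. off).
#' @return List with `r`, `p`, `n`, `df`.
#' @export
pearson_with_p <- function(x, y, bonferroni_m = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y) || n < 3L || !all(is.finite(c(x, y))))
    stop("pearson_with_p: need equal-length finite vectors, n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_with_p: correlation undefined for zero-variance input",
         call. = FALSE)
  r <- stats::cor(x, y)
  df <- n - 2L
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tt), df)
  }
  list(r = r, p = min(1, p * bonferroni_m), n = n, df = df)
}

#' Assemble, score and rank a screening panel
#'
#' Joins UV metrics, antioxidant results and (optionally) viability at the
#' top dose into one record per isolate, applies [select_candidates()],
#' computes the triangle score on the selected records (SPFi normalized to
#' the reference filter when `config$spfi_reference` is set, raw SPFi on
#' the 0-100 scale otherwise) and ranks them.
#'
#' @param records data.frame with at least `isolate_id`, `rsc_dpph`,
#'   `rsc_abts`, `spfi`, `lambda_c_nm`, `uva_uvb_ratio`, optionally
#'   `viability_top_dose`.
#' @param config A [run_config()].
#' @return List with `records` (all, with flags), `ranking` (selected
#'   records with `spfi_pct`, `score`, `rank`) and `audit`.
#' @export
screen_panel <- function(records, config = run_config()) {
  flagged <- select_candidates(records, config)
  sel <- flagged[flagged$selected, , drop = FALSE]
  ref <- config$spfi_reference
  sel$spfi_pct <- if (is.finite(ref) && ref > 0) 100 * sel$spfi / ref else sel$spfi
  sel$score <- mapply(function(s, d, a)
    triangle_score(s, max(d, 0), max(a, 0)),
    sel$spfi_pct, sel$rsc_dpph, sel$rsc_abts)
  list(records = flagged,
       ranking = rank_records(sel),
       audit = attr(flagged, "audit"))
}
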