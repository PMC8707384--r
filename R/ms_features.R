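# Monoisotopic element masses (most abundant isotope; CODATA/IUPAC) and
# the proton mass used for +1 adducts.
ELEMENT_MASSES <- c(H = 1.00782503, C = 12, N = 14.00307401, O = 15.99491462,
                    P = 30.97376151, S = 31.97207069)
PROTON_MASS <- 1.00727646
ACN_MASS <- 2 * 12 + 3 * 1.00782503 + 14.00307401  # acetonitrile C2H3N

# Canonical positive-mode adduct set: label -> neutral mass shift (Da), z = +1.
ADDUCT_SHIFTS <- c("[M+H]+" = PROTON_MASS,
                   "[M+ACN+H]+" = ACN_MASS + PROTON_MASS,
                   "[M+2ACN+H]+" = 2 * ACN_MASS + PROTON_MASS)

#' Parse a molecular formula into element counts
#'
#' Supported elements: C, H, N, O, P, S (nonnegative integer counts).
#'
#' @param formula Formula string such as `"C28H38N4O6"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  formula <- gsub("\\s", "", as.character(formula))
  if (!nzchar(formula)) return(stats::setNames(integer(0L), character(0L)))
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1L]]
  if (paste(toks, collapse = "") != formula)
    stop("formula error: cannot parse '", formula, "'", call. = FALSE)
  counts <- integer(0L)
  for (tok in toks) {
    el <- gsub("[0-9]", "", tok)
    if (!el %in% names(ELEMENT_MASSES))
      stop("formula error: unsupported element '", el, "' in '", formula, "'",
           call. = FALSE)
    n <- gsub("[^0-9]", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' Dot product of element counts with the most-abundant-isotope masses
#' (C 12 exact, H 1.00782503, N 14.00307401, O 15.99491462, P 30.97376151,
#' S 31.97207069).
#'
#' @param formula Formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C34H60N4O10")  # 684.430944
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (!length(counts)) return(0)
  sum(ELEMENT_MASSES[names(counts)] * counts)
}

#' Normalize an adduct label to the canonical set
#'
#' Accepts case and whitespace variants of `[M+H]+`, `[M+ACN+H]+`,
#' `[M+2ACN+H]+`.
#'
#' @param label Adduct label(s).
#' @return Canonical label(s).
#' @export
normalize_adduct <- function(label) {
  key <- toupper(gsub("[[:space:]^]", "", label))
  canon <- names(ADDUCT_SHIFTS)
  idx <- match(key, toupper(canon))
  if (anyNA(idx))
    stop("unknown adduct label(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "),
         "; supported: ", paste(canon, collapse = ", "), call. = FALSE)
  canon[idx]
}

#' Theoretical m/z of an adduct ion
#'
#' Monoisotopic formula mass plus the adduct mass shift
#' (`[M+H]+` 1.007276; `[M+ACN+H]+` 42.033825; `[M+2ACN+H]+` 83.060374),
#' singly charged.
#'
#' @param formula Molecular formula of the neutral compound.
#' @param adduct Adduct label (normalized via [normalize_adduct()]).
#' @param digits Decimals for the reported value (default 4, the
#'   conventional reporting precision); `NA` for full precision.
#' @return Theoretical m/z in Th.
#' @examples
#' adduct_mz("C28H38N4O6", "[M+H]+")  # 527.2864
#' @export
adduct_mz <- function(formula, adduct, digits = 4L) {
  adduct <- normalize_adduct(adduct)
  mz <- monoisotopic_mass(formula) + ADDUCT_SHIFTS[[adduct]]
  if (is.na(digits)) mz else round(mz, digits)
}

#' Mass measurement accuracy in ppm
#'
#' `|observed - calculated| / calculated * 1e6`. The denominator is the
#' calculated m/z, so the function is only approximately symmetric under
#' swapping its arguments.
#'
#' @param mz_observed,mz_calculated m/z values in Th.
#' @return Error in ppm.
#' @export
ppm_error <- function(mz_observed, mz_calculated) {
  if (any(mz_calculated <= 0))
    stop("ppm_error: calculated m/z must be positive", call. = FALSE)
  abs(mz_observed - mz_calculated) / mz_calculated * 1e6
}

#' LC-MS feature table container
#'
#' @param extract_id Extract label.
#' @param feature_id Unique feature identifiers.
#' @param rt_min Retention times in minutes (>= 0).
#' @param mz_observed Observed m/z (> 0).
#' @param formula Optional molecular formulas (`NA` when unannotated).
#' @param adduct Optional adduct labels, normalized on construction.
#' @return Object of class `feature_table` (a data.frame sorted by RT then
#'   m/z).
#' @export
feature_table <- function(extract_id, feature_id, rt_min, mz_observed,
                          formula = NA_character_, adduct = NA_character_) {
  n <- length(feature_id)
  df <- data.frame(feature_id = as.character(feature_id),
                   rt_min = as.numeric(rt_min),
                   mz_observed = as.numeric(mz_observed),
                   formula = rep_len(as.character(formula), n),
                   adduct = rep_len(as.character(adduct), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$feature_id))
    stop("feature_id values must be unique within an extract", call. = FALSE)
  if (any(df$mz_observed <= 0) || any(df$rt_min < 0))
    stop("feature_table: need mz_observed > 0 and rt_min >= 0", call. = FALSE)
  has_adduct <- !is.na(df$adduct)
  df$adduct[has_adduct] <- normalize_adduct(df$adduct[has_adduct])
  df <- df[order(df$rt_min, df$mz_observed), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "extract_id") <- as.character(extract_id)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s: %d features, RT %.2f-%.2f min, m/z %.4f-%.4f\n",
              attr(x, "extract_id"), nrow(x), min(x$rt_min), max(x$rt_min),
              min(x$mz_observed), max(x$mz_observed)))
  invisible(x)
}

#' Read an LC-MS feature table from CSV
#'
#' Needs columns `feature_id`, `rt_min`, `mz_observed`; optional `formula`
#' and `adduct`. Rows whose formula fails to parse are skipped and
#' collected in `attr(, "skipped")` with the parse message.
#'
#' @param path CSV path.
#' @param extract_id Extract label; defaults to the file base name.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, extract_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("feature_id", "rt_min", "mz_observed")
  if (!all(req %in% names(df)))
    stop("feature table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (is.null(extract_id)) extract_id <- sub("\\.[^.]*$", "", basename(path))
  if (!"formula" %in% names(df)) df$formula <- NA_character_
  if (!"adduct" %in% names(df)) df$adduct <- NA_character_
  ok <- rep(TRUE, nrow(df))
  msgs <- character(0L)
  for (i in which(!is.na(df$formula) & nzchar(df$formula))) {
    err <- tryCatch({ parse_formula(df$formula[i]); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(err)) {
      ok[i] <- FALSE
      msgs <- c(msgs, sprintf("row %d (%s): %s", i, df$feature_id[i], err))
    }
  }
  if (length(msgs))
    warning("skipped ", length(msgs), " row(s) with unparseable formulas",
            call. = FALSE)
  ft <- feature_table(extract_id, df$feature_id[ok], df$rt_min[ok],
                      df$mz_observed[ok], df$formula[ok], df$adduct[ok])
  attr(ft, "skipped") <- msgs
  ft
}

#' Fraction of features at or above a mass threshold
#'
#' The share of features whose m/z (or, optionally, adduct-corrected
#' neutral mass) is at or above `threshold`. Molecules above ~330 Da carry
#' a lower risk of skin absorption, so a high fraction is desirable in a
#' topical product.
#'
#' @param table A [feature_table()].
#' @param threshold Mass threshold in Da (default 330).
#' @param neutral Use the adduct-corrected neutral mass where formula and
#'   adduct are known (features lacking either keep observed m/z).
#' @return Percentage in `[0, 100]`.
#' @export
mass_fraction_above <- function(table, threshold = 330, neutral = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table) == 0L)
    stop("mass_fraction_above undefined for an empty feature table", call. = FALSE)
  m <- table$mz_observed
  if (neutral) {
    has <- !is.na(table$adduct)
    m[has] <- m[has] - ADDUCT_SHIFTS[table$adduct[has]]
  }
  100 * sum(m >= threshold) / length(m)
}

#' Match features across extracts into cross-extract groups
#'
#' Greedy nearest-neighbour grouping: features are pooled over all
#' extracts and scanned in ascending m/z; each unassigned feature seeds a
#' group and absorbs, per extract, the unassigned feature closest in m/z
#' among those within the ppm and retention-time windows of the seed.
#' Every feature ends up in exactly one group; the partition is exhaustive
#' and disjoint. No retention-time alignment is attempted (single
#' instrument, single method).
#'
#' @param tables List of [feature_table()]s (>= 2).
#' @param ppm_tol Mass window in ppm (default 10).
#' @param rt_tol Retention-time window in minutes (default 0.2).
#' @return data.frame with one row per feature: `group`, `extract_id`,
#'   `feature_id`, `rt_min`, `mz_observed`; group presence/absence per
#'   extract is summarized by [intersection_counts()].
#' @export
match_features <- function(tables, ppm_tol = 10, rt_tol = 0.2) {
  if (length(tables) < 2L)
    stop("match_features needs at least two feature tables", call. = FALSE)
  pool <- do.call(rbind, lapply(tables, function(t) {
    data.frame(extract_id = attr(t, "extract_id"), feature_id = t$feature_id,
               rt_min = t$rt_min, mz_observed = t$mz_observed,
               stringsAsFactors = FALSE)
  }))
  pool <- pool[order(pool$mz_observed, pool$extract_id, pool$feature_id), ,
               drop = FALSE]
  rownames(pool) <- NULL
  n <- nrow(pool)
  group <- rep(NA_integer_, n)
  g <- 0L
  for (i in seq_len(n)) {
    if (!is.na(group[i])) next
    g <- g + 1L
    group[i] <- g
    tol <- pool$mz_observed[i] * ppm_tol / 1e6
    cand <- which(is.na(group) &
                    abs(pool$mz_observed - pool$mz_observed[i]) <= tol &
                    abs(pool$rt_min - pool$rt_min[i]) <= rt_tol)
    if (!length(cand)) next
    # at most one partner per extract: the nearest in m/z
    for (ex in unique(pool$extract_id[cand])) {
      if (ex == pool$extract_id[i]) next
      sub <- cand[pool$extract_id[cand] == ex]
      best <- sub[which.min(abs(pool$mz_observed[sub] - pool$mz_observed[i]))]
      group[best] <- g
    }
  }
  pool$group <- group
  pool[, c("group", "extract_id", "feature_id", "rt_min", "mz_observed")]
}

#' Exact subset (UpSet-style) intersection counts of feature groups
#'
#' Each group contributes to exactly one subset: the full set of extracts
#' it is present in. Counts therefore sum to the number of groups.
#'
#' @param groups Output of [match_features()].
#' @return data.frame with `subset` (extract ids joined by `"&"`),
#'   `n_extracts`, `count`, sorted by decreasing count.
#' @export
intersection_counts <- function(groups) {
  stopifnot(all(c("group", "extract_id") %in% names(groups)))
  per_group <- vapply(split(groups$extract_id, groups$group), function(e) {
    paste(sort(unique(e)), collapse = "&")
  }, character(1L))
  tab <- table(per_group)
  out <- data.frame(subset = names(tab),
                    n_extracts = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$subset), , drop = FALSE]
}

#' Annotate features against a user-supplied compound table
#'
#' For every feature x adduct combination, candidate compounds whose
#' theoretical adduct m/z lies within the ppm window are collected. The
#' identification level follows the HRMS confidence convention: level 3
#' (putative candidate) when exactly one candidate structure matches,
#' level 4 (unequivocal molecular formula) when several isomeric entries
#' share the matching formula; the isomer count is reported.
#'
#' @param features A [feature_table()].
#' @param compound_table data.frame with columns `name` and `formula`.
#' @param adducts Adduct labels to try (default: the full canonical set).
#' @param ppm_tol Mass window in ppm (default 10).
#' @return List with `candidates` (one row per feature x matching
#'   compound x adduct, with `ppm`) and `summary` (one row per annotated
#'   feature: best formula, `isomer_coincidence`, `identification_level`).
#' @export
annotate_features <- function(features, compound_table,
                              adducts = names(ADDUCT_SHIFTS), ppm_tol = 10) {
  stopifnot(inherits(features, "feature_table"),
            is.data.frame(compound_table))
  empty <- list(
    candidates = data.frame(feature_id = character(0L), name = character(0L),
                            formula = character(0L), adduct = character(0L),
                            mz_calculated = numeric(0L), ppm = numeric(0L)),
    summary = data.frame(feature_id = character(0L), formula = character(0L),
                         adduct = character(0L), isomer_coincidence = integer(0L),
                         identification_level = integer(0L)))
  if (nrow(compound_table) == 0L || nrow(features) == 0L) return(empty)
  adducts <- normalize_adduct(adducts)
  calc <- do.call(rbind, lapply(adducts, function(ad) {
    data.frame(name = compound_table$name, formula = compound_table$formula,
               adduct = ad,
               mz_calculated = vapply(compound_table$formula, function(f)
                 adduct_mz(f, ad, digits = NA), numeric(1L)),
               stringsAsFactors = FALSE)
  }))
  cand_list <- lapply(seq_len(nrow(features)), function(i) {
    ppm <- ppm_error(features$mz_observed[i], calc$mz_calculated)
    hit <- ppm <= ppm_tol
    if (!any(hit)) return(NULL)
    cbind(data.frame(feature_id = features$feature_id[i]),
          calc[hit, , drop = FALSE], ppm = ppm[hit])
  })
  cand <- do.call(rbind, cand_list)
  if (is.null(cand)) return(empty)
  rownames(cand) <- NULL
  summ <- do.call(rbind, lapply(split(cand, cand$feature_id), function(cf) {
    best_formula <- cf$formula[which.min(cf$ppm)]
    sub <- cf[cf$formula == best_formula, , drop = FALSE]
    n_iso <- length(unique(sub$name))
    data.frame(feature_id = cf$feature_id[1L], formula = best_formula,
               adduct = sub$adduct[which.min(sub$ppm)],
               isomer_coincidence = n_iso,
               identification_level = if (n_iso == 1L) 3L else 4L,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(candidates = cand, summary = summ)
}

#' Bundled example feature table (G1225-style annotated features)
#'
#' Loads the packaged 17-feature annotated table (retention time,
#' molecular formula, adduct, observed m/z) shipped under `extdata`.
#'
#' @return A [feature_table()].
#' @export
example_feature_table <- function() {
  read_feature_table(system.file("extdata", "g1225_features.csv",
                                 package = "photoscreen"),
                     extract_id = "G1225")
}
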