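#' Read a microplate assay table from CSV
#'
#' The CSV needs columns `role` (one of `blank`, `sample`, `untreated`,
#' `treated`), `replicate`, `absorbance`, plus `sample_id` for sample and
#' treated rows and `concentration` for treated rows. An optional `assay`
#' column splits a mixed file into one plate per assay.
#'
#' @param path CSV file path.
#' @param assay Assay label attached to the plate (`DPPH`, `ABTS`, `TPC`,
#'   `TFC`, `MTT`, ...); ignored when the file carries an `assay` column,
#'   in which case a named list of plates is returned.
#' @return An `assay_plate` list (or named list of them): radical/content
#'   plates carry `blank_abs` and `sample_abs`; viability plates carry
#'   `untreated_abs` and `treated_abs` keyed by `sample_id` and dose.
#' @export
read_plate_table <- function(path, assay = "DPPH") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty plate file: ", path, call. = FALSE)
  req <- c("role", "absorbance")
  if (!all(req %in% names(df)))
    stop("plate file must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  if ("assay" %in% names(df)) {
    split_df <- split(df[setdiff(names(df), "assay")], df$assay)
    return(lapply(split_df, as_assay_plate, assay = NULL) |>
             (\(x) stats::setNames(x, names(split_df)))())
  }
  as_assay_plate(df, assay = assay)
}

# Build the plate container from a validated long-format data.frame.
as_assay_plate <- function(df, assay = NULL) {
  known <- c("blank", "sample", "untreated", "treated")
  bad <- setdiff(unique(df$role), known)
  if (length(bad))
    stop("unknown role label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(known, collapse = "/"), ")", call. = FALSE)
  df$absorbance <- as.numeric(df$absorbance)
  if (anyNA(df$absorbance)) stop("non-numeric absorbance values", call. = FALSE)
  plate <- list(assay = assay)
  if (any(df$role %in% c("blank", "sample"))) {
    plate$blank_abs <- df$absorbance[df$role == "blank"]
    s <- df[df$role == "sample", , drop = FALSE]
    plate$sample_abs <- split(s$absorbance, s$sample_id)
  }
  if (any(df$role %in% c("untreated", "treated"))) {
    plate$untreated_abs <- df$absorbance[df$role == "untreated"]
    t <- df[df$role == "treated", , drop = FALSE]
    if (nrow(t)) {
      key <- interaction(t$sample_id, t$concentration, drop = TRUE, sep = "@")
      plate$treated_abs <- split(t$absorbance, key)
      plate$treated_key <- unique(data.frame(sample_id = t$sample_id,
                                             concentration = as.numeric(t$concentration),
                                             key = as.character(key)))
    }
  }
  class(plate) <- "assay_plate"
  plate
}

#' @export
print.assay_plate <- function(x, ...) {
  cat(sprintf("<assay_plate>%s: %d blank, %d sample group(s), %d untreated, %d treated group(s)\n",
              if (is.null(x$assay)) "" else paste0(" ", x$assay),
              length(x$blank_abs), length(x$sample_abs),
              length(x$untreated_abs), length(x$treated_abs)))
  invisible(x)
}

#' Per-group mean and SD of a plate
#'
#' @param plate An `assay_plate`.
#' @return data.frame with columns `group`, `n`, `mean`, `sd`.
#' @export
plate_summary <- function(plate) {
  stopifnot(inherits(plate, "assay_plate"))
  groups <- c(list(blank = plate$blank_abs, untreated = plate$untreated_abs),
              plate$sample_abs, plate$treated_abs)
  groups <- groups[!vapply(groups, is.null, logical(1L))]
  groups <- groups[vapply(groups, length, integer(1L)) > 0L]
  data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1L)),
    mean = vapply(groups, mean, numeric(1L)),
    sd = vapply(groups, function(g) if (length(g) > 1L) stats::sd(g) else NA_real_,
                numeric(1L)),
    row.names = NULL
  )
}
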