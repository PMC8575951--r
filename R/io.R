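# Tabular input: per-individual GRS tables, variant weights, and GRS
# computation from dosages.

#' Read a per-individual GRS table
#'
#' Reads a headered CSV or TSV file of per-individual genetic risk scores.
#' The delimiter is inferred from the file extension (`.tsv` / `.txt` ->
#' tab, otherwise comma) unless given. Score cells must be present and
#' numeric; a missing or non-numeric cell is a hard error naming the row.
#'
#' @param path Path to the file.
#' @param score_col,id_col,cohort_col Column names in the file; `cohort_col`
#'   is optional (`NULL` drops it). Defaults `"grs"` and `"id"`.
#' @param delim Field delimiter; inferred from the extension when `NULL`.
#' @return A tibble with columns `id`, `grs` and (if present) `cohort`, in
#'   input order.
#' @export
read_grs <- function(path, score_col = "grs", id_col = "id",
                     cohort_col = NULL, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, col_types = readr::cols(.default = "c"))
  for (col in c(score_col, id_col)) {
    if (!col %in% names(tbl)) {
      abort(sprintf("Column '%s' not found in %s", col, path))
    }
  }
  raw <- tbl[[score_col]]
  scores <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(scores) | is.na(raw) | raw == "")
  if (length(bad) > 0) {
    abort(sprintf(
      "Missing or non-numeric score in column '%s' at data row %s of %s",
      score_col, paste(head(bad, 5), collapse = ", "), path
    ))
  }
  out <- tibble::tibble(id = tbl[[id_col]], grs = scores)
  if (!is.null(cohort_col)) {
    if (!cohort_col %in% names(tbl)) {
      abort(sprintf("Column '%s' not found in %s", cohort_col, path))
    }
    out$cohort <- tbl[[cohort_col]]
  }
  out
}

#' Read a variant-weights table
#'
#' Reads a CSV of per-variant GRS weights with columns `variant`,
#' `effect_allele` and `weight` (the natural log of the odds ratio).
#' Variant ids must be unique and weights finite.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `variant`, `effect_allele`, `weight`.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("variant", "effect_allele", "weight")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(sprintf("Weights table is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(tbl$variant)) abort("Variant ids must be unique.")
  if (anyNA(tbl$weight) || any(!is.finite(tbl$weight))) {
    abort("Weights must be finite.")
  }
  tbl[need]
}

#' Compute GRS from a dosage matrix and variant weights
#'
#' The log-additive GRS of each individual is the sum over variants of the
#' effect-allele dosage multiplied by the variant weight (the natural log of
#' the odds ratio): `score_i = sum_v dosage_iv * weight_v`. Dosages must lie
#' in `[0, 2]` and every variant column must have a weight; matching is by
#' variant id, so column order is irrelevant.
#'
#' @param dosages Numeric matrix (or data frame) of effect-allele dosages,
#'   individuals in rows, variants in columns named by variant id.
#' @param weights A weights table as returned by [read_weights()] (columns
#'   `variant` and `weight`).
#' @return A tibble with columns `id` (row names, or row index) and `grs`.
#' @examples
#' d <- matrix(c(2, 1), nrow = 1, dimnames = list("s1", c("v1", "v2")))
#' w <- tibble::tibble(variant = c("v1", "v2"),
#'                     effect_allele = c("A", "G"),
#'                     weight = c(log(2), log(3)))
#' grs_from_dosages(d, w)
#' @export
grs_from_dosages <- function(dosages, weights) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages))) {
    abort("`dosages` must have variant ids as column names.")
  }
  missing_w <- setdiff(colnames(dosages), weights$variant)
  if (length(missing_w) > 0) {
    abort(sprintf("No weight for variant(s): %s",
                  paste(head(missing_w, 5), collapse = ", ")))
  }
  if (anyNA(dosages) || any(dosages < 0) || any(dosages > 2)) {
    abort("Dosages must lie in [0, 2] with no missing values.")
  }
  w <- weights$weight[match(colnames(dosages), weights$variant)]
  scores <- as.vector(dosages %*% w)
  ids <- rownames(dosages) %||% as.character(seq_len(nrow(dosages)))
  tibble::tibble(id = ids, grs = scores)
}
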