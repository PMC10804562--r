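# Conversions between the wide protein-matrix tibble (user-facing) and the
# numeric matrix (internal). The wide form has a `protein` character column
# followed by one numeric column per sample; missing cells are NA.

#' Convert a wide protein-matrix tibble to a numeric matrix
#'
#' @param tbl Tibble with a `protein` column and numeric sample columns.
#' @return Numeric matrix, proteins as rownames, samples as colnames.
#' @export
tbl_to_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), "protein" %in% names(tbl))
  if (anyDuplicated(tbl$protein)) {
    stop("duplicate protein ids in matrix table", call. = FALSE)
  }
  cols <- setdiff(names(tbl), "protein")
  m <- as.matrix(tbl[, cols, drop = FALSE])
  if (!is.numeric(m) && !is.logical(m)) {
    stop("sample columns must be numeric", call. = FALSE)
  }
  rownames(m) <- tbl$protein
  m
}

#' Convert a numeric matrix to a wide protein-matrix tibble
#'
#' @param m Numeric matrix with protein rownames and sample colnames.
#' @return Tibble with `protein` column first.
#' @export
matrix_to_tbl <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  dplyr::bind_cols(tibble::tibble(protein = rownames(m)),
                   tibble::as_tibble(m))
}

# accept either representation internally
as_protein_matrix <- function(x) {
  if (is.matrix(x)) x else tbl_to_matrix(x)
}

#' Imputation provenance flags of a quantified matrix
#'
#' [impute_knn()] attaches a logical flag table (same shape as the matrix)
#' marking which cells were imputed rather than observed.
#'
#' @param x A matrix tibble returned by [impute_knn()].
#' @return Wide logical tibble, or `NULL` if no flags are attached.
#' @export
imputation_flags <- function(x) {
  attr(x, "imputed")
}

# raw median absolute deviation (no normal-consistency constant): the
# selection thresholds used throughout are raw-MAD cutoffs
raw_mad <- function(x) {
  x <- x[!is.na(x)]
  stats::median(abs(x - stats::median(x)))
}

row_raw_mad <- function(m) {
  med <- matrixStats::rowMedians(m, na.rm = TRUE)
  matrixStats::rowMedians(abs(m - med), na.rm = TRUE)
}
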