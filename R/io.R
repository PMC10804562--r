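# TSV / GMT / newick readers and writers. TSV everywhere (ids in the wild
# contain commas); missing values are empty cells, never sentinel numbers.

write_tsv_na <- function(x, path) {
  readr::write_tsv(x, path, na = "")
  invisible(path)
}

#' Read / write a PSM table
#'
#' PSM TSVs carry plex_id, spectrum_id, peptide, protein_accession,
#' q_value, isolation_interference_pct, and one `intensity_<channel>`
#' column per reporter channel; empty intensity cells mean no signal.
#'
#' @param path File path.
#' @return [read_psm_tsv()]: PSM tibble. Malformed rows (wrong field
#'   count, non-numeric intensities) raise errors citing the line.
#' @export
read_psm_tsv <- function(path) {
  req <- c("plex_id", "spectrum_id", "peptide", "protein_accession",
           "q_value", "isolation_interference_pct")
  tbl <- read_tsv_strict(path, character_cols = req[1:4])
  missing <- setdiff(req, names(tbl))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column '%s'", path, missing[1]),
         call. = FALSE)
  }
  if (!any(grepl("^intensity_", names(tbl)))) {
    stop(sprintf("%s: no intensity_<channel> columns", path), call. = FALSE)
  }
  tbl
}

#' @rdname read_psm_tsv
#' @param psms PSM tibble.
#' @export
write_psm_tsv <- function(psms, path) write_tsv_na(psms, path)

#' Read / write a plex design table
#'
#' Columns: plex_id, channel, sample_id, is_reference.
#' @param path File path.
#' @export
read_design_tsv <- function(path) {
  tbl <- read_tsv_strict(
    path,
    character_cols = c("plex_id", "channel", "sample_id", "is_reference"))
  req <- c("plex_id", "channel", "sample_id", "is_reference")
  missing <- setdiff(req, names(tbl))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column '%s'", path, missing[1]),
         call. = FALSE)
  }
  tbl$is_reference <- as.logical(tbl$is_reference)
  tbl
}

#' @rdname read_design_tsv
#' @param design Design tibble.
#' @export
write_design_tsv <- function(design, path) write_tsv_na(design, path)

#' Read / write a sample annotation table
#'
#' Columns: sample_id, patient, collection_type (ET/ES/BT), level,
#' tumor_cellularity_pct (optional).
#' @param path File path.
#' @export
read_annotation_tsv <- function(path) {
  tbl <- read_tsv_strict(
    path, character_cols = c("sample_id", "patient", "collection_type"))
  req <- c("sample_id", "patient", "collection_type", "level")
  missing <- setdiff(req, names(tbl))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column '%s'", path, missing[1]),
         call. = FALSE)
  }
  bad <- !tbl$collection_type %in% c("ET", "ES", "BT")
  if (any(bad)) {
    stop(sprintf("%s: line %d: collection_type '%s' not one of ET/ES/BT",
                 path, which(bad)[1] + 1L, tbl$collection_type[bad][1]),
         call. = FALSE)
  }
  tbl$level <- as.integer(tbl$level)
  tbl
}

#' @rdname read_annotation_tsv
#' @param annotation Annotation tibble.
#' @export
write_annotation_tsv <- function(annotation, path) {
  write_tsv_na(annotation, path)
}

#' Read / write a wide protein matrix
#'
#' Proteins as rows, header of sample ids, empty cells for missing values.
#' @param path File path.
#' @export
read_matrix_tsv <- function(path) {
  tbl <- read_tsv_strict(path, character_cols = "protein")
  if (names(tbl)[1] != "protein") {
    stop(sprintf("%s: first column must be 'protein'", path), call. = FALSE)
  }
  tbl
}

#' @rdname read_matrix_tsv
#' @param tbl Wide matrix tibble.
#' @export
write_matrix_tsv <- function(tbl, path) write_tsv_na(tbl, path)

# shared strict TSV reader: hard errors with line numbers on ragged rows or
# non-numeric values. Columns are read as text and converted with base R's
# correctly-rounded strtod so that written doubles round-trip bit-exactly.
read_tsv_strict <- function(path, character_cols = character()) {
  tbl <- suppressWarnings(readr::read_tsv(
    path, na = "", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  ))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    stop(sprintf("%s: line %d: malformed row (%s)", path, probs$row[1],
                 probs$expected[1]), call. = FALSE)
  }
  for (cn in setdiff(names(tbl), character_cols)) {
    v <- tbl[[cn]]
    num <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(num)
    if (any(bad)) {
      stop(sprintf("%s: line %d: expected a number in column '%s', got '%s'",
                   path, which(bad)[1] + 1L, cn, v[bad][1]), call. = FALSE)
    }
    tbl[[cn]] <- num
  }
  tbl
}

#' Read / write gene-set GMT files
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`. Lines with fewer
#' than three fields are parse errors citing the line number.
#'
#' @param path File path.
#' @return [read_gmt()]: named list of character feature vectors, with a
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("%s: line %d: GMT lines need name, description and >= 1 member (%d fields found)",
                   path, i, length(fields)), call. = FALSE)
    }
    sets[[fields[1]]] <- fields[-(1:2)]
    desc[fields[1]] <- fields[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional named descriptions (default `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else {
      "na"
    }
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an output manifest with content hashes
#'
#' @param files Character vector of file paths (relative paths are
#'   recorded relative to `root`).
#' @param path Manifest JSON destination.
#' @param root Directory against which file paths are relativized.
#' @param meta Named list of run metadata (seed, parameters) echoed into
#'   the manifest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(files, path, root = dirname(path), meta = list()) {
  md5 <- unname(tools::md5sum(files))
  rel <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", root), "/?"),
             "", files)
  manifest <- list(
    meta = meta,
    files = data.frame(path = rel, md5 = md5, stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
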