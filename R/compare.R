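# Cross-dataset concordant-alteration overlap, cross-platform correlations,
# RPPA preprocessing, and purity association.

#' Preprocess a raw RPPA target-by-sample table
#'
#' Values at or below the detection limit (zero or absent) are replaced by
#' `exp(lod_floor_log)`, abundances are log2-transformed, and each target
#' row is median-centered (idempotent on already-centered data).
#'
#' @param raw Wide tibble with a `target` column and non-negative numeric
#'   sample columns.
#' @param lod_floor_log Natural-log detection floor (default -10: zeros
#'   become `exp(-10)` before the log2 transform).
#' @return Tibble of the same shape, log2 scale, row medians 0.
#' @export
rppa_preprocess <- function(raw, lod_floor_log = -10) {
  stopifnot("target" %in% names(raw))
  m <- as.matrix(raw[, setdiff(names(raw), "target"), drop = FALSE])
  if (any(m < 0, na.rm = TRUE)) {
    stop("raw RPPA values must be non-negative", call. = FALSE)
  }
  all_zero <- rowSums(is.na(m) | m == 0) == ncol(m)
  if (any(all_zero)) {
    warning(sprintf("%d target(s) entirely below detection; retained as constant rows",
                    sum(all_zero)))
  }
  m[is.na(m) | m == 0] <- exp(lod_floor_log)
  m <- log2(m)
  m <- sweep(m, 1L, apply(m, 1L, stats::median))
  out <- dplyr::bind_cols(tibble::tibble(target = raw$target),
                          tibble::as_tibble(m))
  out
}

#' Concordant overlap of two alteration sets
#'
#' Partitions the union of two datasets' significantly altered proteins
#' into: shared with the same fold-change direction, shared with opposite
#' directions (reported explicitly rather than silently dropped), unique
#' to each dataset.
#'
#' @param a,b Alteration-set tibbles (protein, direction, logfc, adj_p),
#'   e.g. from [concordance_filter()].
#' @return Object of class `lmd_overlap`: list with tibbles `shared`
#'   (logfc_a/logfc_b columns), `discordant`, `unique_a`, `unique_b`, and
#'   `counts`.
#' @export
overlap_concordant <- function(a, b) {
  stopifnot(all(c("protein", "direction") %in% names(a)),
            all(c("protein", "direction") %in% names(b)))
  if (anyDuplicated(a$protein) || anyDuplicated(b$protein)) {
    stop("alteration sets must have unique proteins", call. = FALSE)
  }
  if (any(a$direction == 0) || any(b$direction == 0)) {
    stop("alteration directions must be nonzero", call. = FALSE)
  }
  joined <- dplyr::inner_join(a, b, by = "protein",
                              suffix = c("_a", "_b"))
  shared <- joined[joined$direction_a == joined$direction_b, , drop = FALSE]
  discordant <- joined[joined$direction_a != joined$direction_b, , drop = FALSE]
  unique_a <- a[!a$protein %in% b$protein, , drop = FALSE]
  unique_b <- b[!b$protein %in% a$protein, , drop = FALSE]
  counts <- tibble::tibble(
    category = c("shared", "discordant", "unique_a", "unique_b"),
    n = c(nrow(shared), nrow(discordant), nrow(unique_a), nrow(unique_b))
  )
  structure(list(shared = shared, discordant = discordant,
                 unique_a = unique_a, unique_b = unique_b, counts = counts),
            class = "lmd_overlap")
}

#' @export
print.lmd_overlap <- function(x, ...) {
  n <- stats::setNames(x$counts$n, x$counts$category)
  cat(sprintf(
    "<lmd_overlap> shared same-direction: %d | discordant: %d | unique to a: %d | unique to b: %d\n",
    n["shared"], n["discordant"], n["unique_a"], n["unique_b"]))
  invisible(x)
}

#' @rdname overlap_concordant
#' @param x An `lmd_overlap`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.lmd_overlap <- function(x, ...) x$counts

#' Correlation of log fold changes between two datasets
#'
#' Spearman correlation over the proteins present in both alteration sets
#' (all shared proteins by default, concordant-direction only by flag).
#'
#' @param a,b Alteration-set tibbles with `protein` and `logfc` columns.
#' @param same_direction_only Restrict to proteins with matching direction.
#' @return One-row tibble: n, rho, p_value.
#' @export
logfc_correlation <- function(a, b, same_direction_only = FALSE) {
  joined <- dplyr::inner_join(a[, c("protein", "direction", "logfc")],
                              b[, c("protein", "direction", "logfc")],
                              by = "protein", suffix = c("_a", "_b"))
  if (same_direction_only) {
    joined <- joined[joined$direction_a == joined$direction_b, , drop = FALSE]
  }
  if (nrow(joined) < 3L) {
    stop("need at least 3 shared proteins", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(joined$logfc_a, joined$logfc_b, method = "spearman")
  )
  tibble::tibble(n = nrow(joined), rho = unname(ct$estimate),
                 p_value = ct$p.value)
}

#' Cross-platform Spearman correlations
#'
#' Correlates an MS protein matrix with a second-platform matrix (RPPA
#' targets or transcripts) over co-measured features. With
#' `per = "sample"`, every pair of samples (one from each platform) gets a
#' Spearman correlation over the mapped feature pairs; with
#' `per = "feature"`, every mapped feature pair gets a correlation across
#' the shared samples. Many-to-one antibody maps expand to one row per
#' (target, protein) pair.
#'
#' @param x Wide protein-matrix tibble or matrix (`protein` rows).
#' @param y Second-platform wide tibble or matrix; its id column may be
#'   `target` or `protein`.
#' @param feature_map Tibble with `target` and `protein` columns mapping y
#'   features to x features; `NULL` (default) uses identical row ids.
#' @param per `"sample"` or `"feature"`.
#' @param annotation Optional sample annotation; when given, per-sample
#'   rows are annotated with `same_patient`.
#' @return Long tibble of correlations.
#' @export
cross_platform_correlation <- function(x, y, feature_map = NULL,
                                       per = c("sample", "feature"),
                                       annotation = NULL) {
  per <- match.arg(per)
  mx <- as_protein_matrix(x)
  if (is.data.frame(y)) {
    idcol <- intersect(c("target", "protein"), names(y))[1]
    if (is.na(idcol)) stop("y needs a 'target' or 'protein' id column",
                           call. = FALSE)
    my <- as.matrix(y[, setdiff(names(y), idcol), drop = FALSE])
    rownames(my) <- y[[idcol]]
  } else {
    my <- y
  }
  if (is.null(feature_map)) {
    shared <- intersect(rownames(mx), rownames(my))
    feature_map <- tibble::tibble(target = shared, protein = shared)
  }
  feature_map <- feature_map[feature_map$target %in% rownames(my) &
                               feature_map$protein %in% rownames(mx), ,
                             drop = FALSE]
  if (nrow(feature_map) < 3L) {
    stop("fewer than 3 mapped feature pairs", call. = FALSE)
  }
  xm <- mx[feature_map$protein, , drop = FALSE]
  ym <- my[feature_map$target, , drop = FALSE]

  if (per == "sample") {
    cm <- stats::cor(xm, ym, method = "spearman")
    out <- tibble::as_tibble(cm, rownames = "sample_x") |>
      tidyr::pivot_longer(-"sample_x", names_to = "sample_y",
                          values_to = "rho")
    if (!is.null(annotation)) {
      pat <- stats::setNames(annotation$patient, annotation$sample_id)
      out$same_patient <- !is.na(pat[out$sample_x]) &
        !is.na(pat[out$sample_y]) &
        pat[out$sample_x] == pat[out$sample_y]
    }
    out
  } else {
    shared_samples <- intersect(colnames(xm), colnames(ym))
    if (length(shared_samples) < 3L) {
      stop("fewer than 3 shared samples", call. = FALSE)
    }
    rho <- vapply(seq_len(nrow(feature_map)), function(i) {
      suppressWarnings(stats::cor(xm[i, shared_samples], ym[i, shared_samples],
                                  method = "spearman"))
    }, numeric(1))
    tibble::tibble(target = feature_map$target,
                   protein = feature_map$protein,
                   n_samples = length(shared_samples), rho = rho)
  }
}

#' Association of altered proteins with tumor purity
#'
#' Per-protein Spearman correlation of abundance against a per-sample
#' purity fraction, plus an aggregate correlation of the mean abundance of
#' the ET-elevated alteration signature against purity.
#'
#' @param tbl Complete wide matrix tibble or matrix.
#' @param alterations Alteration-set tibble (protein, direction, ...).
#' @param purity Tibble with `sample_id` and `purity` (fraction in
#'   \[0, 1\]) columns; correlations run over these samples.
#' @return List with `per_protein` (protein, direction, rho, p_value) and
#'   `aggregate` (one-row tibble: n_proteins, n_samples, rho, p_value for
#'   the ET-up mean signature).
#' @export
purity_association <- function(tbl, alterations, purity) {
  m <- as_protein_matrix(tbl)
  stopifnot(all(c("sample_id", "purity") %in% names(purity)))
  purity <- purity[purity$sample_id %in% colnames(m), , drop = FALSE]
  if (nrow(purity) < 3L) stop("need at least 3 samples with purity",
                              call. = FALSE)
  if (stats::sd(purity$purity) == 0) {
    stop("purity is constant across samples", call. = FALSE)
  }
  prot <- intersect(alterations$protein, rownames(m))
  if (length(prot) == 0L) stop("no alteration proteins in matrix",
                               call. = FALSE)
  sub <- m[prot, purity$sample_id, drop = FALSE]
  per_protein <- purrr::map_dfr(prot, function(g) {
    ct <- suppressWarnings(
      stats::cor.test(sub[g, ], purity$purity, method = "spearman"))
    tibble::tibble(protein = g,
                   direction = alterations$direction[
                     match(g, alterations$protein)],
                   rho = unname(ct$estimate), p_value = ct$p.value)
  })
  up <- prot[alterations$direction[match(prot, alterations$protein)] > 0]
  if (length(up) == 0L) {
    aggregate <- tibble::tibble(n_proteins = 0L, n_samples = nrow(purity),
                                rho = NA_real_, p_value = NA_real_)
  } else {
    sig <- colMeans(sub[up, , drop = FALSE])
    ct <- suppressWarnings(
      stats::cor.test(sig, purity$purity, method = "spearman"))
    aggregate <- tibble::tibble(n_proteins = length(up),
                                n_samples = nrow(purity),
                                rho = unname(ct$estimate),
                                p_value = ct$p.value)
  }
  list(per_protein = per_protein, aggregate = aggregate)
}
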