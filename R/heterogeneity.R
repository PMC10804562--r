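# Spatial heterogeneity statistics: variable-protein selection, correlation
# clustering, pairwise level correlations, patient dendrograms, and the
# secreted-protein variance test.

#' Select variably abundant proteins by raw MAD
#'
#' Row MAD is `median(|x - median(x)|)` with no normal-consistency scaling
#' constant; proteins with MAD strictly greater than `mad_min` are kept and
#' returned sorted by MAD, descending.
#'
#' @param tbl Complete (post-imputation) wide matrix tibble or matrix.
#' @param mad_min Strict lower MAD cutoff (default 1, the cutoff used for
#'   proteome-wide clustering; 0.5 is typical for smaller effect scales).
#' @return Tibble (protein, mad), MAD descending.
#' @export
mad_select <- function(tbl, mad_min = 1) {
  m <- as_protein_matrix(tbl)
  mads <- row_raw_mad(m)
  out <- tibble::tibble(protein = rownames(m), mad = unname(mads))
  out <- out[out$mad > mad_min, , drop = FALSE]
  dplyr::arrange(out, dplyr::desc(.data$mad), .data$protein)
}

#' Unsupervised hierarchical clustering of samples and proteins
#'
#' Distance is `1 - Pearson correlation` (configurable), linkage is average
#' (UPGMA); matches the defaults of the correlation-clustering tools used
#' for proteome heatmaps. Columns are processed in label order so the
#' result is deterministic.
#'
#' @param tbl Complete wide matrix tibble or matrix.
#' @param proteins Optional protein ids to cluster on (e.g. from
#'   [mad_select()]); default all.
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @param linkage Agglomeration method (default `"average"`).
#' @return Object of class `lmd_clust`: list with `samples` and `proteins`
#'   `hclust` trees.
#' @export
hier_cluster <- function(tbl, proteins = NULL, cor_method = "pearson",
                         linkage = "average") {
  m <- as_protein_matrix(tbl)
  if (!is.null(proteins)) {
    if (is.data.frame(proteins)) proteins <- proteins$protein
    missing <- setdiff(proteins, rownames(m))
    if (length(missing) > 0) {
      stop(sprintf("protein '%s' not in matrix", missing[1]), call. = FALSE)
    }
    m <- m[proteins, , drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 samples and 2 proteins to cluster", call. = FALSE)
  }
  if (anyNA(m)) stop("matrix must be complete (impute first)", call. = FALSE)
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  sample_sd <- apply(m, 2L, stats::sd)
  if (any(sample_sd == 0)) {
    stop(sprintf("sample '%s' has zero variance over the selected proteins",
                 colnames(m)[sample_sd == 0][1]), call. = FALSE)
  }
  protein_sd <- apply(m, 1L, stats::sd)
  if (any(protein_sd == 0)) {
    stop(sprintf("protein '%s' has zero variance",
                 rownames(m)[protein_sd == 0][1]), call. = FALSE)
  }
  hs <- stats::hclust(stats::as.dist(1 - stats::cor(m, method = cor_method)),
                      method = linkage)
  hp <- stats::hclust(stats::as.dist(1 - stats::cor(t(m), method = cor_method)),
                      method = linkage)
  structure(list(samples = hs, proteins = hp, cor_method = cor_method,
                 linkage = linkage),
            class = "lmd_clust")
}

#' @export
print.lmd_clust <- function(x, ...) {
  cat(sprintf("<lmd_clust> %d samples x %d proteins (%s correlation, %s linkage)\n",
              length(x$samples$labels), length(x$proteins$labels),
              x$cor_method, x$linkage))
  invisible(x)
}

#' Cut the sample tree and label clusters by their majority collection type
#'
#' @param clust An `lmd_clust` from [hier_cluster()].
#' @param annotation Sample annotation tibble.
#' @param k Number of clusters (default 2).
#' @return Tibble (sample_id, patient, collection_type, level, cluster,
#'   cluster_majority) where `cluster_majority` is the collection type most
#'   frequent among the non-BT members of that cluster.
#' @export
cluster_assignments <- function(clust, annotation, k = 2L) {
  stopifnot(inherits(clust, "lmd_clust"))
  cl <- stats::cutree(clust$samples, k = k)
  out <- tibble::tibble(sample_id = names(cl), cluster = unname(cl)) |>
    dplyr::left_join(annotation, by = "sample_id") |>
    dplyr::select("sample_id", "patient", "collection_type", "level",
                  "cluster")
  maj <- out |>
    dplyr::filter(.data$collection_type != "BT") |>
    dplyr::count(.data$cluster, .data$collection_type) |>
    dplyr::slice_max(.data$n, n = 1L, by = "cluster", with_ties = FALSE) |>
    dplyr::select("cluster", cluster_majority = "collection_type")
  dplyr::left_join(out, maj, by = "cluster")
}

#' Serialize a clustering tree to newick
#'
#' @param tree An `hclust`, or an `lmd_clust` (whose `which` tree is taken).
#' @param which `"samples"` or `"proteins"` when `tree` is an `lmd_clust`.
#' @return Newick string (with branch lengths from merge heights).
#' @export
as_newick <- function(tree, which = c("samples", "proteins")) {
  if (inherits(tree, "lmd_clust")) tree <- tree[[match.arg(which)]]
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree))
}

#' Pairwise Spearman correlations between sampling levels
#'
#' Spearman correlations (average-rank ties) over all proteins — no MAD
#' cutoff — between every pair of samples within each (patient, collection
#' type) group. Self-correlations are excluded.
#'
#' @param tbl Complete wide matrix tibble or matrix.
#' @param annotation Sample annotation tibble.
#' @param types Collection types to include (default all three).
#' @return Long tibble: patient, collection_type, sample_a, sample_b,
#'   level_a, level_b, rho (one row per unordered pair). Groups of size 1
#'   are skipped with a warning.
#' @export
pairwise_spearman <- function(tbl, annotation, types = c("ET", "ES", "BT")) {
  m <- as_protein_matrix(tbl)
  ann <- annotation[annotation$collection_type %in% types &
                      annotation$sample_id %in% colnames(m), , drop = FALSE]
  groups <- dplyr::distinct(ann, .data$patient, .data$collection_type)
  res <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    ga <- ann[ann$patient == groups$patient[i] &
                ann$collection_type == groups$collection_type[i], , drop = FALSE]
    ga <- ga[order(ga$level), , drop = FALSE]
    if (nrow(ga) < 2L) {
      warning(sprintf("group %s/%s has a single sample; skipped",
                      groups$patient[i], groups$collection_type[i]))
      next
    }
    cm <- stats::cor(m[, ga$sample_id, drop = FALSE], method = "spearman")
    pairs <- which(upper.tri(cm), arr.ind = TRUE)
    res[[i]] <- tibble::tibble(
      patient = groups$patient[i],
      collection_type = groups$collection_type[i],
      sample_a = ga$sample_id[pairs[, 1]],
      sample_b = ga$sample_id[pairs[, 2]],
      level_a = ga$level[pairs[, 1]],
      level_b = ga$level[pairs[, 2]],
      rho = cm[pairs]
    )
  }
  dplyr::bind_rows(res)
}

#' Summarize pairwise correlations per group
#'
#' Median, minimum, and maximum of the off-diagonal pairwise correlations
#' per (patient, collection type), or per collection type with
#' `by = "collection_type"`.
#'
#' @param pairs Output of [pairwise_spearman()].
#' @param by Grouping columns (default patient and collection type).
#' @return Summary tibble with n_pairs, median_rho, min_rho, max_rho.
#' @export
correlation_summary <- function(pairs,
                                by = c("patient", "collection_type")) {
  dplyr::summarise(
    pairs,
    n_pairs = dplyr::n(),
    median_rho = stats::median(.data$rho),
    min_rho = min(.data$rho),
    max_rho = max(.data$rho),
    .by = dplyr::all_of(by)
  )
}

#' Patient-specific dendrogram and ET-vs-ES heterogeneity test
#'
#' For one patient with at least `min_levels` levels in both ET and ES:
#' selects proteins with raw MAD > `mad_min` *within that patient's ET+ES
#' samples*, builds an average-linkage dendrogram on `1 - Spearman`
#' distances, and compares the intra-ET pairwise level correlations against
#' the intra-ES ones with a two-sided Mann-Whitney U test. The collection
#' type with the higher median internal correlation is the more
#' homogeneous one.
#'
#' @param tbl Complete wide matrix tibble or matrix.
#' @param annotation Sample annotation tibble.
#' @param patient Patient id.
#' @param mad_min Within-patient raw-MAD cutoff (default 1).
#' @param min_levels Inclusion rule: minimum levels in both ET and ES
#'   (default 3).
#' @return List with `tree` (hclust), `test` (one-row tibble: patient,
#'   n_proteins, n_et, n_es, statistic, p_value, higher_type, median_et,
#'   median_es), and `pairs`; or `NULL` (with a message) when the
#'   inclusion rule is unmet.
#' @export
patient_dendrogram <- function(tbl, annotation, patient, mad_min = 1,
                               min_levels = 3L) {
  m <- as_protein_matrix(tbl)
  ann <- annotation[annotation$patient == patient &
                      annotation$collection_type %in% c("ET", "ES") &
                      annotation$sample_id %in% colnames(m), , drop = FALSE]
  n_et <- sum(ann$collection_type == "ET")
  n_es <- sum(ann$collection_type == "ES")
  if (n_et < min_levels || n_es < min_levels) {
    message(sprintf(
      "patient %s skipped: %d ET / %d ES levels (need >= %d in both)",
      patient, n_et, n_es, min_levels))
    return(NULL)
  }
  sub <- m[, sort(ann$sample_id), drop = FALSE]
  sel <- mad_select(sub, mad_min = mad_min)
  if (nrow(sel) < 3L) {
    message(sprintf(
      "patient %s skipped: only %d protein(s) pass MAD > %g (need >= 3)",
      patient, nrow(sel), mad_min))
    return(NULL)
  }
  sub <- sub[sel$protein, , drop = FALSE]
  cm <- stats::cor(sub, method = "spearman")
  if (anyNA(cm)) {
    stop(sprintf("undefined correlations within patient %s", patient),
         call. = FALSE)
  }
  tree <- stats::hclust(stats::as.dist(1 - cm), method = "average")
  pairs <- pairwise_spearman(sub, ann, types = c("ET", "ES"))
  et_rho <- pairs$rho[pairs$collection_type == "ET"]
  es_rho <- pairs$rho[pairs$collection_type == "ES"]
  wt <- mann_whitney(et_rho, es_rho)
  med_et <- stats::median(et_rho)
  med_es <- stats::median(es_rho)
  test <- tibble::tibble(
    patient = patient, n_proteins = nrow(sel), n_et = n_et, n_es = n_es,
    statistic = wt$statistic, p_value = wt$p_value,
    higher_type = if (med_et >= med_es) "ET" else "ES",
    median_et = med_et, median_es = med_es
  )
  list(tree = tree, test = test, pairs = pairs)
}

# two-sided Mann-Whitney U via stats::wilcox.test: exact for small untied
# samples, normal approximation with tie correction otherwise
mann_whitney <- function(x, y) {
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Secreted-protein spatial variance test
#'
#' Tests whether proteins flagged as secreted / extracellular (signal
#' peptide) vary more between sampling levels than unflagged proteins.
#' Within each eligible (patient, collection type) scope — patients with at
#' least `min_levels` levels in both ET and ES — each protein's
#' between-level variability is its raw MAD across that patient's levels of
#' that type; the two flag classes are compared by a two-sided
#' Mann-Whitney U test.
#'
#' @param tbl Complete wide matrix tibble or matrix.
#' @param annotation Sample annotation tibble.
#' @param secreted Logical vector named by protein, or a tibble with
#'   `protein` and `secreted` columns (e.g. `truth$proteins`).
#' @param types Collection types to test (default ET and ES).
#' @param min_levels Eligibility: minimum levels in both ET and ES
#'   (default 4, i.e. patients with 4-5 levels of each).
#' @return Tibble with one row per (patient, collection_type):
#'   n_levels, n_secreted, n_other, statistic, p_value, median_secreted,
#'   median_other.
#' @export
secreted_variance_test <- function(tbl, annotation, secreted,
                                   types = c("ET", "ES"), min_levels = 4L) {
  m <- as_protein_matrix(tbl)
  if (is.data.frame(secreted)) {
    flags <- secreted$secreted[match(rownames(m), secreted$protein)]
  } else {
    flags <- secreted[rownames(m)]
  }
  if (anyNA(flags)) {
    stop("secreted flag missing for some proteins in the matrix",
         call. = FALSE)
  }
  if (sum(flags) < 2L || sum(!flags) < 2L) {
    stop("need at least 2 proteins in both the secreted and non-secreted class",
         call. = FALSE)
  }
  ann <- annotation[annotation$sample_id %in% colnames(m), , drop = FALSE]
  lvl_counts <- ann |>
    dplyr::filter(.data$collection_type %in% c("ET", "ES")) |>
    dplyr::count(.data$patient, .data$collection_type)
  eligible <- lvl_counts |>
    tidyr::pivot_wider(names_from = "collection_type", values_from = "n",
                       values_fill = 0L) |>
    dplyr::filter(.data$ET >= min_levels, .data$ES >= min_levels)
  res <- list()
  for (pt in eligible$patient) {
    for (ty in types) {
      ids <- ann$sample_id[ann$patient == pt & ann$collection_type == ty]
      if (length(ids) < 2L) next
      mads <- row_raw_mad(m[, ids, drop = FALSE])
      wt <- mann_whitney(mads[flags], mads[!flags])
      res[[paste(pt, ty)]] <- tibble::tibble(
        patient = pt, collection_type = ty, n_levels = length(ids),
        n_secreted = sum(flags), n_other = sum(!flags),
        statistic = wt$statistic, p_value = wt$p_value,
        median_secreted = stats::median(mads[flags]),
        median_other = stats::median(mads[!flags])
      )
    }
  }
  if (length(res) == 0L) {
    return(tibble::tibble(
      patient = character(), collection_type = character(),
      n_levels = integer(), n_secreted = integer(), n_other = integer(),
      statistic = numeric(), p_value = numeric(),
      median_secreted = numeric(), median_other = numeric()
    ))
  }
  dplyr::bind_rows(res)
}
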