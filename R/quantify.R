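# PSM-level filtering, ratio-to-reference quantitation, protein roll-up,
# median normalization, plex merging, and k-NN imputation.

bind_psms <- function(psms) {
  if (is.data.frame(psms)) return(tibble::as_tibble(psms))
  dplyr::bind_rows(psms)
}

intensity_cols <- function(psms) {
  grep("^intensity_", names(psms), value = TRUE)
}

#' Filter PSMs on identification confidence and signal quality
#'
#' Retains exactly the PSMs that satisfy all of: q-value strictly below
#' `q_max` (FDR filter), isolation interference strictly below
#' `interference_max` (a PSM at exactly the threshold is excluded),
#' a present and positive reference-channel intensity, and signal in at
#' least one non-reference channel. Counts of each exclusion reason are
#' attached as the `"exclusions"` attribute.
#'
#' Multi-accession PSMs (semicolon-separated `protein_accession`) are
#' rejected unless `keep_first = TRUE`, in which case the first accession
#' is kept; shared-peptide razor logic is deliberately out of scope.
#'
#' @param psms PSM tibble (or list of per-plex tibbles, which are bound).
#' @param q_max Strict upper bound on the PSM q-value (default 0.01,
#'   i.e. FDR below one percent).
#' @param interference_max Strict upper bound on isolation interference,
#'   percent (default 50; >= 50 excluded).
#' @param reference_channel Reference channel label (default `"126"`).
#' @param keep_first Keep the first accession of multi-accession rows
#'   instead of erroring.
#' @return Filtered PSM tibble with attribute `"exclusions"` (named counts).
#' @examples
#' co <- simulate_cohort(sim_config(n_patients = 1, n_proteins = 30, seed = 2))
#' kept <- filter_psms(co$psms)
#' attr(kept, "exclusions")
#' @export
filter_psms <- function(psms, q_max = 0.01, interference_max = 50,
                        reference_channel = "126", keep_first = FALSE) {
  psms <- bind_psms(psms)
  ref_col <- paste0("intensity_", reference_channel)
  if (!ref_col %in% names(psms)) {
    stop(sprintf("unknown reference channel label '%s'", reference_channel),
         call. = FALSE)
  }
  multi <- grepl(";", psms$protein_accession, fixed = TRUE)
  if (any(multi)) {
    if (!keep_first) {
      stop(sprintf(
        "%d PSMs map to multiple accessions; set keep_first = TRUE to keep the first",
        sum(multi)
      ), call. = FALSE)
    }
    psms$protein_accession <- sub(";.*$", "", psms$protein_accession)
  }
  icols <- intensity_cols(psms)
  other <- setdiff(icols, ref_col)
  ref <- psms[[ref_col]]
  oth <- as.matrix(psms[, other, drop = FALSE])

  fail_q <- !(psms$q_value < q_max)
  fail_int <- !(psms$isolation_interference_pct < interference_max)
  fail_ref <- is.na(ref) | ref <= 0
  fail_signal <- rowSums(!is.na(oth) & oth > 0) == 0L

  keep <- !(fail_q | fail_int | fail_ref | fail_signal)
  out <- psms[keep, , drop = FALSE]
  attr(out, "exclusions") <- c(
    q_value = sum(fail_q),
    isolation_interference = sum(fail_int & !fail_q),
    no_reference_signal = sum(fail_ref & !fail_q & !fail_int),
    no_other_signal = sum(fail_signal & !fail_q & !fail_int & !fail_ref),
    retained = sum(keep)
  )
  if (nrow(out) == 0L) warning("no PSMs retained after filtering")
  out
}

#' Per-PSM log2 reporter-ion ratios to the reference channel
#'
#' For each filtered PSM and each non-reference channel with signal,
#' computes `log2(intensity_channel / intensity_reference)` and maps the
#' channel to its sample via the plex design. The reference channel itself
#' is dropped; channels without signal yield no row.
#'
#' @param psms Filtered PSM tibble (see [filter_psms()]).
#' @param design Plex-design tibble (plex_id, channel, sample_id,
#'   is_reference).
#' @return Long tibble: plex_id, spectrum_id, protein, sample_id, log2_ratio.
#' @export
psm_ratios <- function(psms, design) {
  psms <- bind_psms(psms)
  stopifnot(all(c("plex_id", "channel", "sample_id", "is_reference") %in%
                  names(design)))
  out <- vector("list", length(unique(psms$plex_id)))
  i <- 0L
  for (plex in unique(psms$plex_id)) {
    i <- i + 1L
    des <- design[design$plex_id == plex, , drop = FALSE]
    if (nrow(des) == 0L) {
      stop(sprintf("plex '%s' missing from design", plex), call. = FALSE)
    }
    ref_ch <- des$channel[des$is_reference]
    if (length(ref_ch) != 1L) {
      stop(sprintf("plex '%s' must have exactly one reference channel", plex),
           call. = FALSE)
    }
    sub <- psms[psms$plex_id == plex, , drop = FALSE]
    ref <- sub[[paste0("intensity_", ref_ch)]]
    if (any(is.na(ref) | ref <= 0)) {
      stop("PSMs with absent or non-positive reference intensity must be removed by filter_psms first",
           call. = FALSE)
    }
    smp <- des[!des$is_reference, , drop = FALSE]
    mat <- as.matrix(sub[, paste0("intensity_", smp$channel), drop = FALSE])
    ratio <- log2(mat / ref)
    colnames(ratio) <- smp$sample_id
    long <- tibble::tibble(
      plex_id = plex,
      spectrum_id = rep(sub$spectrum_id, times = ncol(ratio)),
      protein = rep(sub$protein_accession, times = ncol(ratio)),
      sample_id = rep(colnames(ratio), each = nrow(ratio)),
      log2_ratio = as.vector(ratio)
    )
    out[[i]] <- long[!is.na(long$log2_ratio), , drop = FALSE]
  }
  dplyr::bind_rows(out)
}

#' Roll PSM-level ratios up to protein abundances
#'
#' Per plex, a protein's abundance in a sample is the median of its
#' PSM-level log2 ratios with signal in that sample. Proteins contributing
#' fewer than `min_psms` PSMs in a plex (counted after filtering, per plex)
#' are dropped from that plex entirely.
#'
#' @param ratios Long ratio tibble from [psm_ratios()].
#' @param min_psms Minimum PSM count per protein per plex (default 2).
#' @return Named list of per-plex wide matrix tibbles.
#' @export
rollup_proteins <- function(ratios, min_psms = 2L) {
  dt <- data.table::as.data.table(ratios)
  plex_id <- protein <- spectrum_id <- log2_ratio <- n_psms <- NULL
  counts <- unique(dt[, list(plex_id, protein, spectrum_id)])[
    , list(n_psms = .N), by = list(plex_id, protein)]
  kept <- counts[n_psms >= min_psms, list(plex_id, protein)]
  rolled <- dt[kept, on = c("plex_id", "protein")][
    , list(log2_abundance = stats::median(log2_ratio)),
    by = list(plex_id, protein, sample_id)]
  plexes <- unique(ratios$plex_id)
  out <- lapply(plexes, function(px) {
    sub <- rolled[plex_id == px]
    wide <- data.table::dcast(sub, protein ~ sample_id,
                              value.var = "log2_abundance")
    dplyr::arrange(tibble::as_tibble(wide), .data$protein)
  })
  names(out) <- plexes
  out
}

#' Median-center each sample column
#'
#' Subtracts each sample column's median over observed values, so every
#' column has median 0 afterwards (idempotent).
#'
#' @param tbl Wide protein-matrix tibble (missing cells NA).
#' @return Tibble of the same shape.
#' @export
normalize_medians <- function(tbl) {
  m <- as_protein_matrix(tbl)
  meds <- apply(m, 2L, stats::median, na.rm = TRUE)
  if (any(is.na(meds))) {
    bad <- colnames(m)[is.na(meds)][1]
    stop(sprintf("sample '%s' has no observed values", bad), call. = FALSE)
  }
  out <- matrix_to_tbl(sweep(m, 2L, meds))
  attr(out, "imputed") <- attr(tbl, "imputed")
  out
}

#' Merge per-plex protein matrices into one cohort matrix
#'
#' Takes the union of proteins over plexes; a (protein, sample) cell is
#' missing when the protein was not quantified in that sample's plex.
#' Columns are ordered to follow the annotation when given.
#'
#' @param plex_matrices Named list of wide per-plex matrix tibbles.
#' @param annotation Optional [sample_annotation] tibble used to order and
#'   check sample columns.
#' @return One wide matrix tibble.
#' @export
merge_plexes <- function(plex_matrices, annotation = NULL) {
  all_samples <- unlist(lapply(plex_matrices, function(x) setdiff(names(x), "protein")))
  dup <- all_samples[duplicated(all_samples)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate sample id across plexes: %s", dup[1]),
         call. = FALSE)
  }
  long <- dplyr::bind_rows(lapply(plex_matrices, function(x) {
    tidyr::pivot_longer(x, -"protein", names_to = "sample_id",
                        values_to = "log2_abundance")
  }))
  long <- long[!is.na(long$log2_abundance), , drop = FALSE]
  wide <- tidyr::pivot_wider(long, names_from = "sample_id",
                             values_from = "log2_abundance")
  wide <- dplyr::arrange(wide, .data$protein)
  if (!is.null(annotation)) {
    want <- intersect(annotation$sample_id, names(wide))
    extra <- setdiff(setdiff(names(wide), "protein"), annotation$sample_id)
    if (length(extra) > 0) {
      stop(sprintf("sample '%s' not present in annotation", extra[1]),
           call. = FALSE)
    }
    wide <- wide[, c("protein", want), drop = FALSE]
  }
  wide
}

#' k-nearest-neighbor imputation of a merged protein matrix
#'
#' Proteins observed in fewer than `min_quant_frac` of the samples (or of
#' the patients, by flag) are dropped. For each remaining missing cell
#' (protein g, sample s), the imputed value is the unweighted mean, at s,
#' of the `k` proteins nearest to g — Euclidean distance computed over the
#' samples where both proteins are observed, candidates restricted to
#' proteins observed at s, distance ties broken by protein id order. Cells
#' that were imputed are flagged in the `"imputed"` attribute
#' (see [imputation_flags()]).
#'
#' @param tbl Merged wide matrix tibble with missing cells.
#' @param k Number of neighbors (default 10). If fewer candidates exist,
#'   all are used with a warning.
#' @param min_quant_frac Minimum fraction of samples (default 0.5,
#'   inclusive) in which a protein must be observed to be retained.
#' @param denominator `"samples"` (default) or `"patients"`: whether the
#'   `min_quant_frac` coverage requirement counts individual samples or
#'   patients with at least one observation.
#' @param annotation Required when `denominator = "patients"`.
#' @return Complete wide matrix tibble with the `"imputed"` flag attribute.
#' @export
impute_knn <- function(tbl, k = 10L, min_quant_frac = 0.5,
                       denominator = c("samples", "patients"),
                       annotation = NULL) {
  denominator <- match.arg(denominator)
  m <- as_protein_matrix(tbl)
  obs <- !is.na(m)
  if (denominator == "samples") {
    frac <- rowMeans(obs)
  } else {
    if (is.null(annotation)) {
      stop("annotation required when denominator = 'patients'", call. = FALSE)
    }
    pats <- annotation$patient[match(colnames(m), annotation$sample_id)]
    seen <- rowsum((+obs) |> t(), pats) > 0   # patients x proteins
    frac <- colMeans(seen)
  }
  m <- m[frac >= min_quant_frac, , drop = FALSE]
  obs <- !is.na(m)

  targets <- which(rowSums(!obs) > 0L)
  flags <- !obs
  warned_small_k <- FALSE
  # squared distances over mutually observed columns, for all target rows
  # at once: sum_s o_i o_j (x_i - x_j)^2 = S_i O_j' + O_i S_j' - 2 X_i X_j'
  # with X the zero-filled matrix, O the observation indicator, S = X^2
  x0 <- m
  x0[!obs] <- 0
  o <- obs * 1
  s0 <- x0^2
  d2_all <- s0[targets, , drop = FALSE] %*% t(o) +
    o[targets, , drop = FALSE] %*% t(s0) -
    2 * x0[targets, , drop = FALSE] %*% t(x0)
  shared_all <- o[targets, , drop = FALSE] %*% t(o)
  for (ti in seq_along(targets)) {
    g <- targets[ti]
    d2 <- pmax(d2_all[ti, ], 0)     # clip BLAS round-off
    d2[shared_all[ti, ] == 0] <- Inf
    d2[g] <- Inf
    ord <- order(d2, rownames(m))   # id order breaks distance ties
    for (s in which(!obs[g, ])) {
      cand <- ord[obs[ord, s] & is.finite(d2[ord])]
      if (length(cand) == 0L) {
        stop(sprintf("no imputation candidates for protein '%s' in sample '%s'",
                     rownames(m)[g], colnames(m)[s]), call. = FALSE)
      }
      if (length(cand) < k && !warned_small_k) {
        warning(sprintf(
          "fewer than k = %d candidate neighbors available; using all %d",
          k, length(cand)))
        warned_small_k <- TRUE
      }
      m[g, s] <- mean(m[cand[seq_len(min(k, length(cand)))], s])
    }
  }
  out <- matrix_to_tbl(m)
  attr(out, "imputed") <- matrix_to_tbl(flags * 1) |>
    dplyr::mutate(dplyr::across(-"protein", as.logical))
  out
}

#' Full quantitation of a (simulated or read) PSM cohort
#'
#' Chains [filter_psms()], [psm_ratios()], [rollup_proteins()],
#' [normalize_medians()], [merge_plexes()], and [impute_knn()] into the
#' final complete proteins-by-samples log2 ratio-to-reference matrix.
#'
#' @param psms PSM tibble or per-plex list.
#' @param design Plex-design tibble.
#' @param annotation Sample-annotation tibble.
#' @param q_max,interference_max,reference_channel See [filter_psms()].
#' @param min_psms See [rollup_proteins()].
#' @param k,min_quant_frac,denominator See [impute_knn()].
#' @return List with `matrix` (complete wide tibble, imputation flags
#'   attached), `merged` (pre-imputation matrix with missingness), and
#'   `exclusions` (PSM filter counts).
#' @examples
#' co <- simulate_cohort(sim_config(n_patients = 2, n_proteins = 60, seed = 5))
#' q <- quantify_cohort(co$psms, co$design, co$annotation)
#' dim(q$matrix)
#' @export
quantify_cohort <- function(psms, design, annotation,
                            q_max = 0.01, interference_max = 50,
                            reference_channel = "126", min_psms = 2L,
                            k = 10L, min_quant_frac = 0.5,
                            denominator = "samples") {
  kept <- filter_psms(psms, q_max = q_max, interference_max = interference_max,
                      reference_channel = reference_channel)
  ratios <- psm_ratios(kept, design)
  per_plex <- rollup_proteins(ratios, min_psms = min_psms)
  per_plex <- lapply(per_plex, normalize_medians)
  merged <- merge_plexes(per_plex, annotation)
  imputed <- impute_knn(merged, k = k, min_quant_frac = min_quant_frac,
                        denominator = denominator, annotation = annotation)
  list(matrix = imputed, merged = merged,
       exclusions = attr(kept, "exclusions"))
}
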