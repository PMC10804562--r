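# Synthetic multi-plex LMD-TMT cohort generator with planted ground truth.

#' TMTpro 16-plex channel labels
#'
#' Reporter-ion channel labels in plex order. Channel "126" is reserved for
#' the patient-specific pooled reference sample.
#'
#' @return Character vector of 16 channel labels.
#' @export
tmt_channels <- function() {
  c("126", "127N", "127C", "128N", "128C", "129N", "129C", "130N",
    "130C", "131N", "131C", "132N", "132C", "133N", "133C", "134N")
}

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic LMD-TMT cohort
#' simulator. Defaults emulate a nine-patient study in which each frozen
#' specimen block is sectioned at five spatially distinct sampling levels
#' and harvested three ways per level: enriched tumor epithelium (ET),
#' enriched tumor-involved stroma (ES), and bulk tissue (BT). Each patient
#' is one TMTpro 16-plex with a pooled reference in channel 126.
#'
#' @param n_patients Number of patients (one TMT plex each).
#' @param n_levels Number of spatial sampling levels per specimen block.
#' @param n_proteins Number of simulated proteins.
#' @param psms_per_protein Mean PSM count per protein per plex.
#' @param psm_count_dist `"poisson"` (counts ~ Poisson(psms_per_protein),
#'   minimum 0) or `"constant"` (every protein gets exactly
#'   `psms_per_protein` PSMs; gives complete coverage for round-trip checks).
#' @param frac_de Fraction of proteins with a true ET-vs-ES difference.
#' @param effect_size_log2 Mean absolute true log2 fold change of
#'   differential proteins.
#' @param effect_size_sd Spread (SD) of the absolute true log2 fold change
#'   around its mean; magnitudes are floored at 0.2 so every planted effect
#'   has a stable sign.
#' @param level_drift_sd SD (log2 units) of the per-level spatial drift step.
#' @param drift_model `"random_walk"` (level l depends on level l-1; spatial
#'   autocorrelation across contiguous tissue levels) or `"iid"`.
#' @param noise_sd Per-PSM, per-channel log2 measurement noise SD.
#' @param baseline_sd SD of per-protein baseline log2 abundance.
#' @param patient_effect_sd SD of the per-patient, per-protein baseline shift
#'   (inter-tumor heterogeneity).
#' @param frac_secreted Fraction of proteins flagged as carrying a signal
#'   peptide / extracellular classification.
#' @param secreted_var_inflation Multiplier on `level_drift_sd` for secreted
#'   proteins (planted excess spatial variability).
#' @param frac_missing_per_plex Probability that a protein is entirely
#'   unobserved in a given plex.
#' @param bt_fraction_range Range (min, max) of the per-level BT tumor-cell
#'   fraction; each BT level draws its fraction uniformly from this range.
#' @param et_levels_range,es_levels_range Integer range (min, max) of the
#'   number of levels actually collected per patient for ET and ES; BT is
#'   always collected at all `n_levels`. Collected levels are `1..k`.
#' @param q_fail_frac Fraction of PSMs whose q-value exceeds the downstream
#'   filtering threshold.
#' @param interference_fail_frac Fraction of PSMs with isolation
#'   interference at or above the downstream filtering threshold.
#' @param frac_signal_missing Probability that a reporter channel of a PSM
#'   lacks signal (missing intensity).
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#'
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(n_patients = 2, n_proteins = 50, seed = 7)
#' @export
sim_config <- function(n_patients = 9L,
                       n_levels = 5L,
                       n_proteins = 2000L,
                       psms_per_protein = 4,
                       psm_count_dist = c("poisson", "constant"),
                       frac_de = 0.10,
                       effect_size_log2 = 1.5,
                       effect_size_sd = 0.3,
                       level_drift_sd = 0.15,
                       drift_model = c("random_walk", "iid"),
                       noise_sd = 0.3,
                       baseline_sd = 1.0,
                       patient_effect_sd = 0.3,
                       frac_secreted = 0.2,
                       secreted_var_inflation = 2.0,
                       frac_missing_per_plex = 0.1,
                       bt_fraction_range = c(0.15, 0.99),
                       et_levels_range = c(4L, 5L),
                       es_levels_range = c(2L, 5L),
                       q_fail_frac = 0.05,
                       interference_fail_frac = 0.05,
                       frac_signal_missing = 0.02,
                       seed = 1L) {
  psm_count_dist <- match.arg(psm_count_dist)
  drift_model <- match.arg(drift_model)
  cfg <- list(
    n_patients = as.integer(n_patients), n_levels = as.integer(n_levels),
    n_proteins = as.integer(n_proteins), psms_per_protein = psms_per_protein,
    psm_count_dist = psm_count_dist, frac_de = frac_de,
    effect_size_log2 = effect_size_log2, effect_size_sd = effect_size_sd,
    level_drift_sd = level_drift_sd, drift_model = drift_model,
    noise_sd = noise_sd, baseline_sd = baseline_sd,
    patient_effect_sd = patient_effect_sd, frac_secreted = frac_secreted,
    secreted_var_inflation = secreted_var_inflation,
    frac_missing_per_plex = frac_missing_per_plex,
    bt_fraction_range = as.numeric(bt_fraction_range),
    et_levels_range = as.integer(et_levels_range),
    es_levels_range = as.integer(es_levels_range),
    q_fail_frac = q_fail_frac,
    interference_fail_frac = interference_fail_frac,
    frac_signal_missing = frac_signal_missing,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_patients >= 1L, cfg$n_levels >= 1L, cfg$n_proteins >= 1L,
    cfg$psms_per_protein >= 1, cfg$effect_size_log2 > 0,
    cfg$effect_size_sd >= 0, cfg$level_drift_sd >= 0, cfg$noise_sd >= 0,
    cfg$baseline_sd >= 0, cfg$patient_effect_sd >= 0,
    cfg$secreted_var_inflation > 0,
    length(cfg$bt_fraction_range) == 2L,
    cfg$bt_fraction_range[1] <= cfg$bt_fraction_range[2]
  )
  fracs <- c(cfg$frac_de, cfg$frac_secreted, cfg$frac_missing_per_plex,
             cfg$bt_fraction_range, cfg$q_fail_frac,
             cfg$interference_fail_frac, cfg$frac_signal_missing)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all fractions in a sim_config must lie in [0, 1]", call. = FALSE)
  }
  for (rng in list(cfg$et_levels_range, cfg$es_levels_range)) {
    if (length(rng) != 2L || rng[1] < 1L || rng[2] > cfg$n_levels ||
        rng[1] > rng[2]) {
      stop("level ranges must satisfy 1 <= min <= max <= n_levels",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

sample_id <- function(patient, type, level) {
  sprintf("%s_%s_L%d", patient, type, as.integer(level))
}

#' Simulate latent per-level abundance profiles and ground truth
#'
#' Draws the latent (noise-free) log2 abundance of every protein in every
#' (patient, collection type, sampling level) cell of the study design,
#' together with the planted ground truth used to test downstream stages.
#' ET and ES baselines differ by the planted log2 fold change on
#' differential proteins; each (patient, type) pair then drifts across
#' levels by a random walk (SD `level_drift_sd`, inflated for secreted
#' proteins). The BT profile at level l is the *linear-scale* mixture
#' `f * 2^ET + (1 - f) * 2^ES` with `f` the level's tumor-cell fraction,
#' stored back in log2 — physical admixture of cell populations is additive
#' in ion counts, not in log space.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `lmd_truth`: a list with tibbles
#'   `proteins` (protein, true_logfc, de, secreted),
#'   `mixing` (patient, level, tumor_fraction),
#'   `profiles` (patient, collection_type, level, protein, log2_abundance),
#'   `annotation` (the [sample_annotation] of emitted samples), and the
#'   configuration.
#' @export
simulate_latent_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_proteins
  L <- cfg$n_levels
  proteins <- sprintf("PROT%05d", seq_len(G))
  patients <- sprintf("PT%02d", seq_len(cfg$n_patients))

  secreted <- stats::runif(G) < cfg$frac_secreted
  n_de <- round(cfg$frac_de * G)
  de_idx <- sort(sample.int(G, n_de))
  true_logfc <- numeric(G)
  if (n_de > 0) {
    mag <- pmax(stats::rnorm(n_de, cfg$effect_size_log2, cfg$effect_size_sd),
                0.2)
    sgn <- sample(c(-1, 1), n_de, replace = TRUE)
    true_logfc[de_idx] <- sgn * mag
  }
  baseline <- stats::rnorm(G, 0, cfg$baseline_sd)
  drift_sd <- cfg$level_drift_sd *
    ifelse(secreted, cfg$secreted_var_inflation, 1)

  # incomplete collection design: ET/ES may have < n_levels levels
  rint <- function(rng) {
    if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
  }

  prof_list <- vector("list", cfg$n_patients)
  mix_list <- vector("list", cfg$n_patients)
  annot_list <- vector("list", cfg$n_patients)
  for (pi in seq_len(cfg$n_patients)) {
    pt <- patients[pi]
    n_et <- rint(cfg$et_levels_range)
    n_es <- rint(cfg$es_levels_range)
    pat_eff <- stats::rnorm(G, 0, cfg$patient_effect_sd)
    base_es <- baseline + pat_eff
    base_et <- base_es + true_logfc

    walk <- function(base) {
      # G x L latent profile: random walk or iid deviations around baseline
      steps <- matrix(stats::rnorm(G * L), G, L) * drift_sd
      if (cfg$drift_model == "random_walk") {
        base + t(apply(steps, 1L, cumsum))
      } else {
        base + steps
      }
    }
    et <- walk(base_et)
    es <- walk(base_es)
    f <- stats::runif(L, cfg$bt_fraction_range[1], cfg$bt_fraction_range[2])
    bt <- log2(sweep(2^et, 2L, f, `*`) + sweep(2^es, 2L, 1 - f, `*`))

    mix_list[[pi]] <- tibble::tibble(patient = pt, level = seq_len(L),
                                     tumor_fraction = f)
    prof_list[[pi]] <- tibble::tibble(
      patient = pt,
      collection_type = rep(c("ET", "ES", "BT"), each = G * L),
      level = rep(rep(seq_len(L), each = G), times = 3L),
      protein = rep(proteins, times = 3L * L),
      log2_abundance = c(et, es, bt)
    )
    cellularity <- function(type, lev) {
      switch(type,
        ET = stats::runif(length(lev), 88, 99),
        ES = stats::runif(length(lev), 2, 12),
        BT = 100 * f[lev]
      )
    }
    annot_list[[pi]] <- dplyr::bind_rows(
      tibble::tibble(collection_type = "ET", level = seq_len(n_et)),
      tibble::tibble(collection_type = "ES", level = seq_len(n_es)),
      tibble::tibble(collection_type = "BT", level = seq_len(L))
    ) |>
      dplyr::mutate(
        patient = pt,
        sample_id = sample_id(pt, .data$collection_type, .data$level),
        tumor_cellularity_pct = unlist(purrr::map2(
          .data$collection_type, .data$level,
          function(ty, lv) cellularity(ty, lv)
        ))
      ) |>
      dplyr::select("sample_id", "patient", "collection_type", "level",
                    "tumor_cellularity_pct")
  }

  structure(
    list(
      proteins = tibble::tibble(protein = proteins, true_logfc = true_logfc,
                                de = true_logfc != 0, secreted = secreted),
      mixing = dplyr::bind_rows(mix_list),
      profiles = dplyr::bind_rows(prof_list),
      annotation = dplyr::bind_rows(annot_list),
      config = cfg
    ),
    class = "lmd_truth"
  )
}

#' @export
print.lmd_truth <- function(x, ...) {
  cat(sprintf(
    "<lmd_truth> %d proteins (%d differential, %d secreted), %d patients, %d samples\n",
    nrow(x$proteins), sum(x$proteins$de), sum(x$proteins$secreted),
    length(unique(x$annotation$patient)), nrow(x$annotation)
  ))
  invisible(x)
}

# latent linear-scale intensity matrix (proteins x samples) for one patient,
# restricted to the samples actually collected
latent_linear_for_patient <- function(truth, pt) {
  ann <- dplyr::filter(truth$annotation, .data$patient == pt)
  prof <- dplyr::filter(truth$profiles, .data$patient == pt) |>
    dplyr::mutate(sample_id = sample_id(.data$patient,
                                        .data$collection_type, .data$level)) |>
    dplyr::filter(.data$sample_id %in% ann$sample_id)
  wide <- tidyr::pivot_wider(
    prof[, c("protein", "sample_id", "log2_abundance")],
    names_from = "sample_id", values_from = "log2_abundance"
  )
  m <- as.matrix(wide[, ann$sample_id, drop = FALSE])
  rownames(m) <- wide$protein
  2^m
}

#' Emit per-plex PSM tables from latent profiles
#'
#' Materializes one patient-specific TMT plex per patient: channel "126"
#' carries the patient's pooled reference (mean linear-scale intensity over
#' all of that patient's collected samples); the remaining channels carry
#' the ET/ES/BT level samples. Each protein receives a number of PSMs drawn
#' from the configured count distribution; each PSM's reporter intensity in
#' a channel is the latent linear intensity times a shared per-PSM
#' ionization factor times per-channel multiplicative log-normal noise
#' `2^N(0, noise_sd)`. Nuisance q-values and isolation-interference values
#' are drawn independently of abundance, with configured fractions failing
#' the downstream filter thresholds so the filters are exercised. Per-plex
#' protein dropout removes all of a protein's PSMs from a plex with
#' probability `frac_missing_per_plex`.
#'
#' @param truth An `lmd_truth` from [simulate_latent_profiles()].
#' @param cfg The same [sim_config()] (seeded; emission uses `seed + 1`).
#' @return A list with `psms` (named list of per-plex PSM tibbles),
#'   `design` (plex-design tibble: plex_id, channel, sample_id,
#'   is_reference), and `annotation`.
#' @export
emit_psm_tables <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "lmd_truth"))
  set.seed(cfg$seed + 1L)
  channels <- tmt_channels()
  patients <- unique(truth$annotation$patient)
  G <- cfg$n_proteins
  proteins <- truth$proteins$protein

  psms <- list()
  design <- list()
  for (pt in patients) {
    ann <- dplyr::filter(truth$annotation, .data$patient == pt)
    n_ch <- nrow(ann) + 1L
    if (n_ch > length(channels)) {
      stop(sprintf(
        "patient %s needs %d channels but a TMTpro plex has only %d",
        pt, n_ch, length(channels)
      ), call. = FALSE)
    }
    plex <- paste0("plex_", pt)
    lin <- latent_linear_for_patient(truth, pt)   # G x samples, linear scale
    pool <- rowMeans(lin)                         # pooled reference channel
    lin_all <- cbind(pool, lin)
    ch_used <- channels[seq_len(n_ch)]
    colnames(lin_all) <- ch_used

    design[[plex]] <- tibble::tibble(
      plex_id = plex,
      channel = ch_used,
      sample_id = c(paste0(pt, "_pool"), ann$sample_id),
      is_reference = c(TRUE, rep(FALSE, nrow(ann)))
    )

    n_psm <- switch(cfg$psm_count_dist,
      poisson = stats::rpois(G, cfg$psms_per_protein),
      constant = rep(as.integer(round(cfg$psms_per_protein)), G)
    )
    # plex-wide protein dropout
    dropped <- stats::runif(G) < cfg$frac_missing_per_plex
    n_psm[dropped] <- 0L
    idx <- rep.int(seq_len(G), n_psm)
    n_rows <- length(idx)
    if (n_rows == 0L) {
      psms[[plex]] <- empty_psm_table(ch_used)
      next
    }

    ionization <- 2^stats::rnorm(n_rows, 10, 1)   # cancels in channel ratios
    noise <- if (cfg$noise_sd > 0) {
      matrix(2^stats::rnorm(n_rows * n_ch, 0, cfg$noise_sd), n_rows, n_ch)
    } else {
      matrix(1, n_rows, n_ch)
    }
    inten <- lin_all[idx, , drop = FALSE] * noise * ionization
    if (cfg$frac_signal_missing > 0) {
      inten[matrix(stats::runif(n_rows * n_ch) < cfg$frac_signal_missing,
                   n_rows, n_ch)] <- NA_real_
    }
    colnames(inten) <- paste0("intensity_", ch_used)

    q <- ifelse(stats::runif(n_rows) < cfg$q_fail_frac,
                stats::runif(n_rows, 0.01, 0.5),
                stats::runif(n_rows, 0, 0.0095))
    interf <- ifelse(stats::runif(n_rows) < cfg$interference_fail_frac,
                     stats::runif(n_rows, 50, 95),
                     stats::runif(n_rows, 0, 45))

    psms[[plex]] <- dplyr::bind_cols(
      tibble::tibble(
        plex_id = plex,
        spectrum_id = sprintf("%s_scan%06d", plex, seq_len(n_rows)),
        peptide = sprintf("PEP_%s_%d", proteins[idx],
                          sequence_within(idx)),
        protein_accession = proteins[idx],
        q_value = q,
        isolation_interference_pct = interf
      ),
      tibble::as_tibble(inten)
    )
  }
  list(psms = psms, design = dplyr::bind_rows(design),
       annotation = truth$annotation)
}

# 1,2,3,... within runs of equal values (idx is sorted by construction)
sequence_within <- function(idx) {
  stats::ave(idx, idx, FUN = seq_along)
}

empty_psm_table <- function(ch_used) {
  out <- tibble::tibble(
    plex_id = character(), spectrum_id = character(), peptide = character(),
    protein_accession = character(), q_value = numeric(),
    isolation_interference_pct = numeric()
  )
  for (ch in ch_used) out[[paste0("intensity_", ch)]] <- numeric()
  out
}

#' Simulate a full cohort (latent profiles + PSM tables)
#'
#' Convenience wrapper: [simulate_latent_profiles()] followed by
#' [emit_psm_tables()].
#'
#' @param cfg A [sim_config()].
#' @return An object of class `lmd_cohort`: list with `truth`, `psms`,
#'   `design`, `annotation`, `config`.
#' @examples
#' co <- simulate_cohort(sim_config(n_patients = 2, n_proteins = 40, seed = 3))
#' names(co$psms)
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  truth <- simulate_latent_profiles(cfg)
  emitted <- emit_psm_tables(truth, cfg)
  structure(
    list(truth = truth, psms = emitted$psms, design = emitted$design,
         annotation = emitted$annotation, config = cfg),
    class = "lmd_cohort"
  )
}

#' @export
print.lmd_cohort <- function(x, ...) {
  cat(sprintf("<lmd_cohort> %d plexes, %d samples, %d proteins, %d PSMs\n",
              length(x$psms), nrow(x$annotation), x$config$n_proteins,
              sum(vapply(x$psms, nrow, integer(1)))))
  invisible(x)
}

#' Latent ratio-to-reference protein matrix
#'
#' The noise-free log2 ratio of each collected sample to its patient's
#' pooled reference — what a perfect quantitation of the simulated cohort
#' would recover before column-median normalization. Useful as a fast,
#' PSM-free entry point to the downstream statistics.
#'
#' @param truth An `lmd_truth`.
#' @param noise_sd Optional additive log2 Gaussian noise applied to each
#'   cell (0 = latent values themselves). Uses the truth's seed offset by 2.
#' @return A wide protein-matrix tibble (`protein` column + one numeric
#'   column per sample).
#' @export
latent_protein_matrix <- function(truth, noise_sd = 0) {
  stopifnot(inherits(truth, "lmd_truth"))
  patients <- unique(truth$annotation$patient)
  mats <- lapply(patients, function(pt) {
    lin <- latent_linear_for_patient(truth, pt)
    log2(lin / rowMeans(lin))
  })
  m <- do.call(cbind, mats)
  if (noise_sd > 0) {
    set.seed(truth$config$seed + 2L)
    m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m), ncol(m))
  }
  matrix_to_tbl(m)
}
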