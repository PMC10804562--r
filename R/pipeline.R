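# End-to-end driver: simulate -> quantify -> heterogeneity -> differential
# -> admixture -> compare, with a hashed output manifest.

#' Pipeline configuration
#'
#' Assembles and validates the full set of stage toggles and parameters.
#' Unknown keys are rejected. The `compare` stage of a purely synthetic run
#' associates the concordant alteration set with the ground-truth BT
#' purity; cross-dataset overlap needs a second alteration set and is
#' driven separately via [overlap_concordant()].
#'
#' @param sim A [sim_config()] (its seed is the run seed unless
#'   overridden in [run_pipeline()]).
#' @param stages Character vector of stages to run, in order, from
#'   `c("simulate", "quantify", "heterogeneity", "differential",
#'   "admixture", "compare")`.
#' @param q_max,interference_max,min_psms,knn_k,min_quant_frac Quantitation
#'   parameters (see [filter_psms()], [rollup_proteins()], [impute_knn()]).
#' @param mad_min Raw-MAD cutoff for cohort-level clustering (default 0.5,
#'   suited to the simulated effect scale; see the methods vignette).
#' @param dendro_mad_min Within-patient raw-MAD cutoff for patient
#'   dendrograms (default 1).
#' @param alpha BH-adjusted-p cutoff for the concordance filter.
#' @param ssgsea_alpha ssGSEA rank-weight exponent.
#' @param n_signature Proteins per ground-truth signature set.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("simulate", "quantify",
                                       "heterogeneity", "differential",
                                       "admixture", "compare"),
                            q_max = 0.01, interference_max = 50,
                            min_psms = 2L, knn_k = 10L,
                            min_quant_frac = 0.5,
                            mad_min = 0.5, dendro_mad_min = 1,
                            alpha = 0.05, ssgsea_alpha = 0.25,
                            n_signature = 50L) {
  all_stages <- c("simulate", "quantify", "heterogeneity", "differential",
                  "admixture", "compare")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) {
    stop(sprintf("unknown stage '%s'", bad[1]), call. = FALSE)
  }
  stopifnot(inherits(sim, "sim_config"),
            q_max > 0, q_max <= 1, interference_max > 0,
            interference_max <= 100, min_psms >= 1,
            knn_k >= 1, min_quant_frac >= 0, min_quant_frac <= 1,
            mad_min >= 0, dendro_mad_min >= 0,
            alpha > 0, alpha < 1, ssgsea_alpha >= 0, n_signature >= 1)
  structure(list(
    sim = sim, stages = stages, q_max = q_max,
    interference_max = interference_max, min_psms = as.integer(min_psms),
    knn_k = as.integer(knn_k), min_quant_frac = min_quant_frac,
    mad_min = mad_min, dendro_mad_min = dendro_mad_min, alpha = alpha,
    ssgsea_alpha = ssgsea_alpha, n_signature = as.integer(n_signature)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `sim`
#' key holds [sim_config()] arguments. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "sim")
  bad <- setdiff(names(raw), c(known, "sim"))
  if (length(bad) > 0) {
    stop(sprintf("unknown configuration key '%s'", bad[1]), call. = FALSE)
  }
  sim_args <- raw$sim %||% list()
  bad_sim <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(bad_sim) > 0) {
    stop(sprintf("unknown sim key '%s'", bad_sim[1]), call. = FALSE)
  }
  args <- raw[setdiff(names(raw), "sim")]
  args$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order, writing every output as TSV /
#' GMT / newick / JSON under `outdir` and recording an MD5-hashed manifest
#' (`manifest.json`). A failing stage aborts with an error naming the
#' stage. With a fixed seed the run is fully deterministic: running twice
#' yields hash-identical manifests.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if absent).
#' @param seed Optional integer overriding the simulation seed.
#' @return Invisibly, a list with `manifest` (path, md5 tibble), `outdir`,
#'   and the in-memory stage `results`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) {
    config$sim$seed <- as.integer(seed)
  }
  stages <- config$stages
  needs_matrix <- intersect(stages, c("heterogeneity", "differential",
                                      "admixture", "compare"))
  if (length(needs_matrix) > 0 && !"quantify" %in% stages &&
      !file.exists(file.path(outdir, "quantify", "matrix.tsv"))) {
    stop(sprintf(
      "stage '%s' needs a quantified matrix: enable the quantify stage or provide %s",
      needs_matrix[1], file.path(outdir, "quantify", "matrix.tsv")),
      call. = FALSE)
  }
  if ("quantify" %in% stages && !"simulate" %in% stages &&
      !dir.exists(file.path(outdir, "simulate"))) {
    stop("quantify needs PSM inputs: enable the simulate stage or provide <outdir>/simulate/",
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  res <- list()
  emit <- function(writer, obj, ...) {
    path <- file.path(...)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    writer(obj, path)
    files <<- c(files, path)
    path
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      co <- simulate_cohort(config$sim)
      res$cohort <<- co
      d <- file.path(outdir, "simulate")
      for (plex in names(co$psms)) {
        emit(write_psm_tsv, co$psms[[plex]], d, paste0(plex, "_psms.tsv"))
      }
      emit(write_design_tsv, co$design, d, "plex_design.tsv")
      emit(write_annotation_tsv, co$annotation, d, "sample_annotation.tsv")
      emit(write_tsv_na, co$truth$proteins, d, "truth_proteins.tsv")
      emit(write_tsv_na, co$truth$mixing, d, "truth_mixing.tsv")
    })
  }

  if ("quantify" %in% stages) {
    run_stage("quantify", function() {
      if (is.null(res$cohort)) {
        d <- file.path(outdir, "simulate")
        psm_files <- list.files(d, pattern = "_psms\\.tsv$",
                                full.names = TRUE)
        psms <- lapply(psm_files, read_psm_tsv)
        design <- read_design_tsv(file.path(d, "plex_design.tsv"))
        annotation <- read_annotation_tsv(
          file.path(d, "sample_annotation.tsv"))
      } else {
        psms <- res$cohort$psms
        design <- res$cohort$design
        annotation <- res$cohort$annotation
      }
      res$annotation <<- annotation
      q <- quantify_cohort(
        psms, design, annotation, q_max = config$q_max,
        interference_max = config$interference_max,
        min_psms = config$min_psms, k = config$knn_k,
        min_quant_frac = config$min_quant_frac)
      res$quant <<- q
      d <- file.path(outdir, "quantify")
      emit(write_matrix_tsv, q$matrix, d, "matrix.tsv")
      emit(write_matrix_tsv, imputation_flags(q$matrix), d,
           "imputation_flags.tsv")
      emit(write_tsv_na,
           tibble::tibble(reason = names(q$exclusions),
                          n = unname(q$exclusions)),
           d, "psm_filter_counts.tsv")
    })
  }

  get_matrix <- function() {
    if (is.null(res$quant)) {
      res$quant <<- list(matrix = read_matrix_tsv(
        file.path(outdir, "quantify", "matrix.tsv")))
    }
    res$quant$matrix
  }
  get_annotation <- function() {
    if (is.null(res$annotation)) {
      res$annotation <<- read_annotation_tsv(
        file.path(outdir, "simulate", "sample_annotation.tsv"))
    }
    res$annotation
  }
  get_truth <- function() {
    if (!is.null(res$cohort)) res$cohort$truth else NULL
  }

  if ("heterogeneity" %in% stages) {
    run_stage("heterogeneity", function() {
      mat <- get_matrix()
      ann <- get_annotation()
      d <- file.path(outdir, "heterogeneity")
      sel <- mad_select(mat, mad_min = config$mad_min)
      emit(write_tsv_na, sel, d, "mad_selected.tsv")
      cl <- hier_cluster(mat, proteins = sel)
      emit(function(o, p) writeLines(o, p), as_newick(cl, "samples"),
           d, "sample_dendrogram.nwk")
      emit(function(o, p) writeLines(o, p), as_newick(cl, "proteins"),
           d, "protein_dendrogram.nwk")
      assign2 <- cluster_assignments(cl, ann, k = 2L)
      emit(write_tsv_na, assign2, d, "cluster_assignments_k2.tsv")
      pairs <- pairwise_spearman(mat, ann)
      emit(write_tsv_na, pairs, d, "pairwise_spearman.tsv")
      emit(write_tsv_na, correlation_summary(pairs), d,
           "pairwise_summary.tsv")
      dendros <- list()
      for (pt in unique(ann$patient)) {
        pd <- patient_dendrogram(mat, ann, pt,
                                 mad_min = config$dendro_mad_min)
        if (is.null(pd)) next
        emit(function(o, p) writeLines(o, p), as_newick(pd$tree),
             d, sprintf("dendrogram_%s.nwk", pt))
        dendros[[pt]] <- pd$test
      }
      if (length(dendros) > 0) {
        emit(write_tsv_na, dplyr::bind_rows(dendros), d,
             "patient_dendrogram_tests.tsv")
      }
      truth <- get_truth()
      if (!is.null(truth)) {
        sv <- secreted_variance_test(mat, ann, truth$proteins)
        emit(write_tsv_na, sv, d, "secreted_variance_tests.tsv")
        res$secreted <<- sv
      }
      res$het <<- list(selected = sel, clusters = cl, assignments = assign2,
                       pairs = pairs)
    })
  }

  if ("differential" %in% stages) {
    run_stage("differential", function() {
      mat <- get_matrix()
      ann <- get_annotation()
      d <- file.path(outdir, "differential")
      fit <- moderated_ttest(mat, ann)
      plfc <- per_patient_logfc(mat, ann)
      alt <- concordance_filter(fit, plfc, alpha = config$alpha)
      emit(write_tsv_na, tidy(fit), d, "differential_table.tsv")
      emit(write_tsv_na, tidyr::pivot_wider(plfc, names_from = "patient",
                                            values_from = "logfc"),
           d, "per_patient_logfc.tsv")
      emit(write_tsv_na, alt, d, "alteration_set.tsv")
      res$diff <<- list(fit = fit, per_patient = plfc, alterations = alt)
    })
  }

  if ("admixture" %in% stages) {
    run_stage("admixture", function() {
      truth <- get_truth()
      if (is.null(truth)) {
        stop("admixture stage on a synthetic run needs the simulate stage in the same call")
      }
      mat <- get_matrix()
      d <- file.path(outdir, "admixture")
      sigs <- truth_signatures(truth, n_per_set = config$n_signature)
      emit(function(o, p) write_gmt(o, p), sigs, d, "signatures.gmt")
      scores <- ssgsea_score(mat, sigs, alpha = config$ssgsea_alpha)
      emit(write_tsv_na,
           tidyr::pivot_wider(scores, names_from = "signature",
                              values_from = "score"),
           d, "ssgsea_scores.tsv")
      rec <- purity_recovery(scores, truth, "Stroma")
      emit(write_tsv_na, rec$data, d, "stroma_purity_scatter.tsv")
      emit(write_tsv_na,
           tibble::tibble(signature = "Stroma", rho = rec$rho,
                          p_value = rec$p_value),
           d, "purity_recovery.tsv")
      res$admix <<- list(signatures = sigs, scores = scores,
                         recovery = rec)
    })
  }

  if ("compare" %in% stages) {
    run_stage("compare", function() {
      truth <- get_truth()
      if (is.null(truth) || is.null(res$diff)) {
        stop("compare stage on a synthetic run needs the simulate and differential stages")
      }
      mat <- get_matrix()
      d <- file.path(outdir, "compare")
      bt <- truth$annotation[truth$annotation$collection_type == "BT", ] |>
        dplyr::left_join(truth$mixing, by = c("patient", "level"))
      pa <- purity_association(
        mat, res$diff$alterations,
        tibble::tibble(sample_id = bt$sample_id, purity = bt$tumor_fraction))
      emit(write_tsv_na, pa$per_protein, d, "purity_per_protein.tsv")
      emit(write_tsv_na, pa$aggregate, d, "purity_aggregate.tsv")
      res$compare <<- pa
    })
  }

  meta <- list(
    package_version = as.character(utils::packageVersion("lmdhet")),
    seed = config$sim$seed,
    stages = stages,
    parameters = config[setdiff(names(config), c("sim", "stages"))],
    sim = unclass(config$sim)
  )
  manifest_path <- file.path(outdir, "manifest.json")
  manifest <- write_manifest(sort(files), manifest_path, root = outdir,
                             meta = meta)
  log_path <- file.path(outdir, "run_log.txt")
  writeLines(c(
    sprintf("lmdhet %s", meta$package_version),
    sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("seed: %d", config$sim$seed),
    sprintf("stages: %s", paste(stages, collapse = ", ")),
    sprintf("outputs: %d files (see manifest.json)", length(files))
  ), log_path)
  invisible(list(manifest = manifest, outdir = outdir, results = res))
}
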