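# ET-vs-ES differential abundance: empirical-Bayes moderated t-statistics,
# per-patient log fold changes, the all-patient sign-concordance filter,
# and pooled Wilcoxon marker tests.

#' Empirical-Bayes moderated t-test (ET vs ES)
#'
#' Fits, per protein, a linear model of log2 abundance on collection type
#' with patient as an additive blocking covariate (blocking can be turned
#' off to pool all samples), and computes moderated t-statistics: residual
#' variances are shrunk toward a pooled prior estimated by matching the
#' first two moments of `log s^2` (digamma/trigamma inversion), giving the
#' posterior variance `s2_post = (d0*s0^2 + df*s^2) / (d0 + df)` and
#' `t = logfc / (sqrt(s2_post) * c)` with `c` the contrast's unscaled
#' standard error, referred to a t distribution on `d0 + df` degrees of
#' freedom. P-values are Benjamini-Hochberg adjusted across proteins.
#'
#' @param tbl Complete wide matrix tibble or matrix.
#' @param annotation Sample annotation tibble; only ET and ES samples are
#'   used.
#' @param block_patient Include patient as a blocking covariate
#'   (default TRUE; the design is a paired multi-plex cohort).
#' @param prior_df Optional forced prior degrees of freedom `d0`:
#'   `0` gives the classical (unmoderated) t-test, `Inf` full shrinkage to
#'   the pooled prior variance; default `NULL` estimates `d0` from the data.
#' @return Object of class `lmd_diff`: list with `table` (tibble: protein,
#'   logfc, s2, s2_post, df, t, p_value, adj_p), `prior_df`, `prior_var`,
#'   `df_residual`, `n_samples`. Use [generics::tidy()] / [generics::glance()].
#' @examples
#' co <- simulate_cohort(sim_config(n_patients = 3, n_proteins = 80, seed = 4))
#' mat <- latent_protein_matrix(co$truth, noise_sd = 0.2)
#' fit <- moderated_ttest(mat, co$annotation)
#' glance(fit)
#' @export
moderated_ttest <- function(tbl, annotation, block_patient = TRUE,
                            prior_df = NULL) {
  m <- as_protein_matrix(tbl)
  if (anyNA(m)) stop("matrix must be complete (impute first)", call. = FALSE)
  ann <- annotation[annotation$collection_type %in% c("ET", "ES") &
                      annotation$sample_id %in% colnames(m), , drop = FALSE]
  if (!any(ann$collection_type == "ET") || !any(ann$collection_type == "ES")) {
    stop("both ET and ES samples are required", call. = FALSE)
  }
  y <- m[, ann$sample_id, drop = FALSE]
  type <- factor(ann$collection_type, levels = c("ES", "ET"))
  x <- if (block_patient && length(unique(ann$patient)) > 1L) {
    stats::model.matrix(~ factor(ann$patient) + type)
  } else {
    stats::model.matrix(~ type)
  }
  n <- nrow(x)
  qr_x <- qr(x)
  df <- n - qr_x$rank
  if (df == 0L) stop("saturated design: zero residual degrees of freedom",
                     call. = FALSE)
  fit <- stats::lm.fit(x, t(y))
  coefs <- fit$coefficients
  ci <- which(colnames(x) == "typeET")
  logfc <- coefs[ci, ]
  s2 <- colSums(fit$residuals^2) / df
  if (any(!is.finite(s2))) stop("non-finite residual variance", call. = FALSE)
  xtxi <- chol2inv(qr.R(qr_x))
  c_se <- sqrt(xtxi[ci, ci])

  eb <- squeeze_var(s2, df, prior_df = prior_df)
  t_mod <- logfc / (sqrt(eb$s2_post) * c_se)
  df_total <- df + eb$prior_df
  p <- 2 * stats::pt(-abs(t_mod), df = if (is.finite(df_total)) df_total else Inf)
  adj_p <- stats::p.adjust(p, method = "BH")

  structure(list(
    table = tibble::tibble(
      protein = colnames(coefs), logfc = unname(logfc), s2 = unname(s2),
      s2_post = unname(eb$s2_post), df = df, t = unname(t_mod),
      p_value = unname(p), adj_p = unname(adj_p)
    ),
    prior_df = eb$prior_df, prior_var = eb$prior_var,
    df_residual = df, n_samples = n, block_patient = block_patient
  ), class = "lmd_diff")
}

# Empirical-Bayes variance shrinkage by moment matching on log s^2.
# With z = log(s2), E[z] = log(s0^2) + digamma(df/2) - log(df/2)
#                        - digamma(d0/2) + log(d0/2)
# and Var[z] = trigamma(df/2) + trigamma(d0/2); solve for (d0, s0^2).
squeeze_var <- function(s2, df, prior_df = NULL) {
  s2 <- pmax(s2, 1e-300)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  if (!is.null(prior_df)) {
    d0 <- prior_df
  } else {
    evar <- stats::var(e)
    rhs <- evar - trigamma(df / 2)
    d0 <- if (rhs <= 0) Inf else 2 * trigamma_inverse(rhs)
  }
  s02 <- if (is.finite(d0) && d0 > 0) {
    exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    exp(emean)  # limit of the moment relation as d0 -> Inf; unused at d0 = 0
  }
  s2_post <- if (d0 == 0) {
    s2
  } else if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else {
    (d0 * s02 + df * s2) / (d0 + df)
  }
  list(prior_df = d0, prior_var = s02, s2_post = s2_post)
}

# Newton inversion of trigamma on (0, Inf)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' @export
print.lmd_diff <- function(x, ...) {
  cat(sprintf(
    "<lmd_diff> %d proteins, %d samples; prior df = %.3g, prior var = %.3g; %d at BH < 0.05\n",
    nrow(x$table), x$n_samples, x$prior_df, x$prior_var,
    sum(x$table$adj_p < 0.05)
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname moderated_ttest
#' @param x An `lmd_diff` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.lmd_diff <- function(x, ...) x$table

#' @rdname moderated_ttest
#' @exportS3Method generics::glance
glance.lmd_diff <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$table), n_samples = x$n_samples,
    df_residual = x$df_residual, prior_df = x$prior_df,
    prior_var = x$prior_var, n_significant = sum(x$table$adj_p < 0.05),
    block_patient = x$block_patient
  )
}

#' Per-patient ET-vs-ES log fold changes
#'
#' `logFC(patient, protein) = median over ET levels - median over ES
#' levels` of log2 abundance. Patients missing either group are excluded
#' with a warning.
#'
#' @param tbl Complete wide matrix tibble or matrix.
#' @param annotation Sample annotation tibble.
#' @return Long tibble: patient, protein, logfc.
#' @export
per_patient_logfc <- function(tbl, annotation) {
  m <- as_protein_matrix(tbl)
  ann <- annotation[annotation$collection_type %in% c("ET", "ES") &
                      annotation$sample_id %in% colnames(m), , drop = FALSE]
  res <- list()
  for (pt in unique(ann$patient)) {
    et <- ann$sample_id[ann$patient == pt & ann$collection_type == "ET"]
    es <- ann$sample_id[ann$patient == pt & ann$collection_type == "ES"]
    if (length(et) == 0L || length(es) == 0L) {
      warning(sprintf("patient %s lacks an ET or ES sample; excluded", pt))
      next
    }
    lfc <- matrixStats::rowMedians(m[, et, drop = FALSE]) -
      matrixStats::rowMedians(m[, es, drop = FALSE])
    res[[pt]] <- tibble::tibble(patient = pt, protein = rownames(m),
                                logfc = unname(lfc))
  }
  dplyr::bind_rows(res)
}

#' All-patient sign-concordance filter
#'
#' Keeps proteins that are significant after BH adjustment
#' (`adj_p < alpha`) *and* whose per-patient log fold changes share one
#' strict nonzero sign across every patient; an exactly zero per-patient
#' logFC counts as discordant.
#'
#' @param diff An `lmd_diff` (or its tidied table).
#' @param patient_logfc Output of [per_patient_logfc()].
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param dataset Optional dataset label attached to the result.
#' @return Alteration-set tibble: protein, direction (+1/-1), logfc,
#'   adj_p — the sign-concordant significantly altered proteins.
#' @export
concordance_filter <- function(diff, patient_logfc, alpha = 0.05,
                               dataset = NULL) {
  tab <- if (inherits(diff, "lmd_diff")) diff$table else diff
  conc <- patient_logfc |>
    dplyr::summarise(
      concordant = all(.data$logfc > 0) || all(.data$logfc < 0),
      direction = sign(.data$logfc[1]),
      .by = "protein"
    )
  out <- tab |>
    dplyr::inner_join(conc, by = "protein") |>
    dplyr::filter(.data$adj_p < alpha, .data$concordant) |>
    dplyr::select("protein", "direction", "logfc", "adj_p") |>
    dplyr::arrange(.data$protein)
  if (!is.null(dataset)) attr(out, "dataset") <- dataset
  out
}

#' Pooled Wilcoxon rank-sum test for one marker protein
#'
#' Two-sided rank-sum test comparing the protein's abundance in all ET
#' samples against all ES samples, pooled across patients.
#'
#' @param tbl Complete wide matrix tibble or matrix.
#' @param annotation Sample annotation tibble.
#' @param protein Protein id.
#' @return One-row tibble: protein, n_et, n_es, direction (sign of the
#'   median difference), statistic, p_value. Constant pooled values give
#'   p = 1 with a warning.
#' @export
wilcoxon_marker <- function(tbl, annotation, protein) {
  m <- as_protein_matrix(tbl)
  if (!protein %in% rownames(m)) {
    stop(sprintf("protein '%s' not in matrix", protein), call. = FALSE)
  }
  ann <- annotation[annotation$collection_type %in% c("ET", "ES") &
                      annotation$sample_id %in% colnames(m), , drop = FALSE]
  et <- m[protein, ann$sample_id[ann$collection_type == "ET"]]
  es <- m[protein, ann$sample_id[ann$collection_type == "ES"]]
  if (length(et) < 2L || length(es) < 2L) {
    stop("need at least 2 samples in each group", call. = FALSE)
  }
  if (stats::sd(c(et, es)) == 0) {
    warning("constant pooled values; p = 1")
    return(tibble::tibble(protein = protein, n_et = length(et),
                          n_es = length(es), direction = 0,
                          statistic = NA_real_, p_value = 1))
  }
  wt <- mann_whitney(et, es)
  tibble::tibble(
    protein = protein, n_et = length(et), n_es = length(es),
    direction = sign(stats::median(et) - stats::median(es)),
    statistic = wt$statistic, p_value = wt$p_value
  )
}
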