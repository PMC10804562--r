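sim_matrix <- function(n_patients = 4, n_proteins = 150, seed = 31,
                       noise_sd = 0.25) {
  cfg <- sim_config(n_patients = n_patients, n_proteins = n_proteins,
                    seed = seed)
  truth <- simulate_latent_profiles(cfg)
  list(mat = latent_protein_matrix(truth, noise_sd = noise_sd),
       ann = truth$annotation, truth = truth)
}

test_that("prior_df = 0 reduces the moderated t to the classical t", {
  d <- sim_matrix(n_proteins = 1000, seed = 41)
  fit0 <- moderated_ttest(d$mat, d$ann, prior_df = 0)
  tab <- tidy(fit0)
  # classical t recomputed per protein with lm()
  m <- tbl_to_matrix(d$mat)
  ann <- d$ann[d$ann$collection_type %in% c("ET", "ES"), ]
  type <- factor(ann$collection_type, levels = c("ES", "ET"))
  pat <- factor(ann$patient)
  idx <- sample(nrow(tab), 25)
  for (i in idx) {
    fit_lm <- stats::lm(m[tab$protein[i], ann$sample_id] ~ pat + type)
    tt <- summary(fit_lm)$coefficients["typeET", ]
    expect_equal(tab$t[i], unname(tt["t value"]), tolerance = 1e-10)
    expect_equal(tab$logfc[i], unname(tt["Estimate"]), tolerance = 1e-10)
    expect_equal(tab$p_value[i], unname(tt["Pr(>|t|)"]), tolerance = 1e-10)
  }
})

test_that("prior_df = Inf shrinks every posterior variance to the prior", {
  d <- sim_matrix(seed = 43)
  fit <- moderated_ttest(d$mat, d$ann, prior_df = Inf)
  expect_true(all(abs(tidy(fit)$s2_post - fit$prior_var) < 1e-12))
})

test_that("posterior variances lie between s2 and the prior variance", {
  d <- sim_matrix(seed = 47)
  fit <- moderated_ttest(d$mat, d$ann)
  tab <- tidy(fit)
  lo <- pmin(tab$s2, fit$prior_var) - 1e-12
  hi <- pmax(tab$s2, fit$prior_var) + 1e-12
  expect_true(all(tab$s2_post >= lo & tab$s2_post <= hi))
  expect_gt(fit$prior_df, 0)
})

test_that("moderated t matches limma's empirical-Bayes fit", {
  skip_if_not_installed("limma")
  d <- sim_matrix(n_proteins = 600, seed = 53)
  fit <- moderated_ttest(d$mat, d$ann)
  m <- tbl_to_matrix(d$mat)
  ann <- d$ann[d$ann$collection_type %in% c("ET", "ES"), ]
  design <- stats::model.matrix(
    ~ factor(ann$patient) + factor(ann$collection_type, c("ES", "ET")))
  lf <- limma::eBayes(limma::lmFit(m[, ann$sample_id], design))
  ci <- ncol(design)
  tab <- tidy(fit)
  expect_equal(fit$prior_df, lf$df.prior, tolerance = 1e-6)
  expect_equal(fit$prior_var, lf$s2.prior, tolerance = 1e-6)
  expect_equal(tab$t, lf$t[tab$protein, ci], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(tab$p_value, lf$p.value[tab$protein, ci], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("null proteins reject at the nominal rate", {
  # pure null matrix: patient blocks + noise, no type effect
  set.seed(59)
  n_prot <- 4000
  grid <- expand.grid(patient = sprintf("PT%02d", 1:4),
                      type = c("ET", "ES"), level = 1:3,
                      stringsAsFactors = FALSE)
  ids <- sprintf("%s_%s_L%d", grid$patient, grid$type, grid$level)
  ann <- annotation_from_names(ids)
  m <- matrix(rnorm(n_prot * length(ids), 0, 0.4), n_prot, length(ids),
              dimnames = list(sprintf("P%05d", 1:n_prot), ids))
  pat_eff <- matrix(rnorm(n_prot * 4, 0, 0.5), n_prot, 4)
  for (j in seq_along(ids)) {
    m[, j] <- m[, j] + pat_eff[, match(ann$patient[j],
                                       sprintf("PT%02d", 1:4))]
  }
  fit <- moderated_ttest(m, ann)
  rate <- mean(tidy(fit)$p_value < 0.05)
  ci <- stats::qbinom(c(0.005, 0.995), n_prot, 0.05) / n_prot
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("swapping ET and ES labels flips signs and preserves p-values", {
  d <- sim_matrix(seed = 61)
  fit <- moderated_ttest(d$mat, d$ann)
  ann_sw <- d$ann
  ann_sw$collection_type <- c(ET = "ES", ES = "ET",
                              BT = "BT")[ann_sw$collection_type]
  fit_sw <- moderated_ttest(d$mat, ann_sw)
  expect_equal(tidy(fit)$logfc, -tidy(fit_sw)$logfc, tolerance = 1e-12)
  expect_equal(tidy(fit)$t, -tidy(fit_sw)$t, tolerance = 1e-12)
  expect_equal(tidy(fit)$p_value, tidy(fit_sw)$p_value, tolerance = 1e-12)
})

test_that("per_patient_logfc is the difference of group medians", {
  ids <- c("PT01_ET_L1", "PT01_ET_L2", "PT01_ET_L3",
           "PT01_ES_L1", "PT01_ES_L2", "PT02_ET_L1", "PT02_BT_L1")
  m <- matrix(0, 1, 7, dimnames = list("P1", ids))
  m[1, ] <- c(1.0, 1.2, 1.4, 0.0, 0.2, 3, 9)
  ann <- annotation_from_names(ids)
  expect_warning(lfc <- per_patient_logfc(m, ann), "PT02")
  expect_equal(lfc$logfc[lfc$patient == "PT01"], 1.2 - 0.1)
  expect_false("PT02" %in% lfc$patient)
  # equal groups give 0; single levels give the plain difference
  m2 <- matrix(c(2, 2, 5, 1), 1, 4,
               dimnames = list("P1", c("PT01_ET_L1", "PT01_ES_L1",
                                       "PT02_ET_L1", "PT02_ES_L1")))
  lfc2 <- per_patient_logfc(m2, annotation_from_names(colnames(m2)))
  expect_equal(lfc2$logfc, c(0, 4))
})

test_that("concordance_filter requires significance and a shared strict sign", {
  tab <- tibble::tibble(
    protein = c("A", "B", "C", "D"),
    logfc = c(2, 1.5, -1, 0.5),
    s2 = 0.1, s2_post = 0.1, df = 10, t = 5,
    p_value = c(0.001, 0.0005, 0.001, 0.2),
    adj_p = c(0.01, 0.06, 0.004, 0.4)
  )
  plfc <- tidyr::expand_grid(patient = c("PT01", "PT02", "PT03"),
                             protein = c("A", "B", "C", "D")) |>
    dplyr::mutate(logfc = dplyr::case_when(
      protein == "A" ~ 1,                       # concordant, significant
      protein == "B" ~ 1,                       # concordant, adj_p = 0.06
      protein == "C" & patient == "PT03" ~ 0.1, # discordant
      protein == "C" ~ -1,
      TRUE ~ 1
    ))
  out <- concordance_filter(tab, plfc, alpha = 0.05)
  expect_equal(out$protein, "A")
  expect_equal(out$direction, 1)
  # zero per-patient logFC counts as discordant
  plfc0 <- plfc
  plfc0$logfc[plfc0$protein == "A" & plfc0$patient == "PT02"] <- 0
  expect_equal(nrow(concordance_filter(tab, plfc0, alpha = 0.05)), 0L)
  # patient order never matters
  out2 <- concordance_filter(tab, plfc[sample(nrow(plfc)), ], alpha = 0.05)
  expect_equal(out, out2)
})

test_that("wilcoxon_marker gives the exact extreme-configuration p-value", {
  ids <- c(sprintf("PT%02d_ET_L1", 1:8), sprintf("PT%02d_ES_L1", 1:8))
  m <- matrix(c(8:1 + 10, 8:1), 1, 16, dimnames = list("MUC16", ids))
  ann <- annotation_from_names(ids)
  res <- wilcoxon_marker(m, ann, "MUC16")
  expect_equal(res$p_value, 2 / choose(16, 8), tolerance = 1e-12)
  expect_equal(res$direction, 1)
  # identical groups: p = 1
  m2 <- matrix(rep(c(5, 3, 1, 2), 4), 1, 16, dimnames = list("MUC16", ids))
  res2 <- suppressWarnings(wilcoxon_marker(m2, ann, "MUC16"))
  expect_gte(res2$p_value, 0.9)
  # constant values warn with p = 1
  m3 <- matrix(1, 1, 16, dimnames = list("MUC16", ids))
  expect_warning(res3 <- wilcoxon_marker(m3, ann, "MUC16"), "constant")
  expect_equal(res3$p_value, 1)
})

test_that("planted markers reach significance on a default-size cohort", {
  d <- sim_matrix(n_patients = 8, n_proteins = 300, seed = 67)
  up <- d$truth$proteins
  marker <- up$protein[which.max(up$true_logfc)]
  res <- wilcoxon_marker(d$mat, d$ann, marker)
  expect_lt(res$p_value, 1e-4)
  expect_equal(res$direction, 1)
})
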