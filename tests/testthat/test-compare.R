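alt_set <- function(proteins, directions, logfc = directions) {
  tibble::tibble(protein = proteins, direction = directions,
                 logfc = logfc, adj_p = 0.01)
}

test_that("rppa_preprocess floors, logs and median-centers targets", {
  raw <- tibble::tibble(target = c("AKT", "ERK"),
                        s1 = c(2, 0), s2 = c(4, 3), s3 = c(8, 5))
  out <- rppa_preprocess(raw)
  expect_equal(unlist(out[out$target == "AKT", -1], use.names = FALSE),
               c(-1, 0, 1))
  # zero becomes log2(e^-10) before centering
  erk_raw <- log2(c(exp(-10), 3, 5))
  expect_equal(unlist(out[out$target == "ERK", -1], use.names = FALSE),
               erk_raw - stats::median(erk_raw))
  # idempotent once centered
  out2 <- rppa_preprocess(
    dplyr::mutate(out, dplyr::across(-"target", ~ 2^.x)))
  expect_equal(out2, out, tolerance = 1e-12)
  # all-zero target warns but is kept
  raw_zero <- tibble::tibble(target = "DEAD", s1 = 0, s2 = 0)
  expect_warning(kept <- rppa_preprocess(raw_zero), "below detection")
  expect_equal(nrow(kept), 1L)
  expect_error(rppa_preprocess(tibble::tibble(target = "X", s1 = -1)),
               "non-negative")
})

test_that("overlap_concordant partitions the union by protein and sign", {
  a <- alt_set(c("P1", "P2", "P3"), c(1, -1, 1))
  b <- alt_set(c("P2", "P3", "P4"), c(-1, -1, 1))
  ov <- overlap_concordant(a, b)
  expect_equal(ov$shared$protein, "P2")
  expect_equal(ov$discordant$protein, "P3")
  expect_equal(ov$unique_a$protein, "P1")
  expect_equal(ov$unique_b$protein, "P4")
  counts <- tidy(ov)
  union_n <- length(union(a$protein, b$protein))
  expect_equal(sum(counts$n), union_n)
  # a vs a: everything shared
  ov2 <- overlap_concordant(a, a)
  expect_equal(nrow(ov2$shared), 3L)
  expect_equal(nrow(ov2$unique_a) + nrow(ov2$unique_b) +
                 nrow(ov2$discordant), 0L)
  # disjoint sets share nothing
  ov3 <- overlap_concordant(a, alt_set("P9", 1))
  expect_equal(nrow(ov3$shared), 0L)
  expect_error(overlap_concordant(alt_set("P1", 0), b), "nonzero")
})

test_that("logfc_correlation recovers perfect and inverted agreement", {
  a <- alt_set(paste0("P", 1:6), rep(1, 6), logfc = c(1, 2, 3, 4, 5, 6))
  b_same <- a
  expect_equal(logfc_correlation(a, b_same)$rho, 1)
  b_flip <- a
  b_flip$logfc <- -b_flip$logfc
  expect_equal(logfc_correlation(a, b_flip)$rho, -1)
  expect_error(logfc_correlation(a[1:2, ], b_same[1:2, ]), "at least 3")
})

test_that("two noisy realizations of one planted truth agree on logFCs", {
  run_once <- function(seed) {
    cfg <- sim_config(n_patients = 4, n_proteins = 300, seed = 3)
    truth <- simulate_latent_profiles(cfg)
    truth$config$seed <- seed             # same truth, independent noise
    mat <- latent_protein_matrix(truth, noise_sd = 0.3)
    fit <- moderated_ttest(mat, truth$annotation)
    concordance_filter(fit, per_patient_logfc(mat, truth$annotation))
  }
  a <- run_once(1001)
  b <- run_once(2002)
  res <- logfc_correlation(a, b)
  expect_gt(res$rho, 0.8)
  expect_gt(res$n, 10)
})

test_that("cross_platform_correlation matches hand-built ranks", {
  m <- toy_matrix(5, 4, seed = 103)
  # platform y = x restricted: self-correlations are 1
  per_s <- cross_platform_correlation(m, m, per = "sample")
  self <- per_s[per_s$sample_x == per_s$sample_y, ]
  expect_equal(self$rho, rep(1, 4))
  # monotone transform changes nothing
  y2 <- exp(m / 2)
  rownames(y2) <- rownames(m)
  per_s2 <- cross_platform_correlation(m, y2, per = "sample")
  expect_equal(per_s$rho, per_s2$rho, tolerance = 1e-12)
  # hand-computed per-sample value via rank correlation
  got <- per_s$rho[per_s$sample_x == "S01" & per_s$sample_y == "S02"]
  expect_equal(got, oracle_spearman(m[, "S01"], m[, "S02"]))
  # per-feature with an antibody map (many-to-one)
  fmap <- tibble::tibble(target = c("ab1", "ab2", "ab2b"),
                         protein = c("P001", "P002", "P002"))
  y <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("ab1", "ab2", "ab2b"), colnames(m)))
  per_f <- cross_platform_correlation(m, y, feature_map = fmap,
                                      per = "feature")
  expect_equal(nrow(per_f), 3L)
  expect_equal(per_f$rho[1], oracle_spearman(m["P001", ], y["ab1", ]))
  expect_error(cross_platform_correlation(m, y,
                                          feature_map = fmap[1, ],
                                          per = "feature"),
               "fewer than 3")
})

test_that("purity_association is exact for monotone planted relationships", {
  cfg <- sim_config(n_patients = 3, n_proteins = 100, level_drift_sd = 0,
                    noise_sd = 0, seed = 17)
  truth <- simulate_latent_profiles(cfg)
  mat <- tbl_to_matrix(latent_protein_matrix(truth))
  bt <- truth$annotation[truth$annotation$collection_type == "BT", ] |>
    dplyr::left_join(truth$mixing, by = c("patient", "level"))
  # restrict to one patient so the pooled-reference scaling is shared
  bt1 <- bt[bt$patient == "PT01", ]
  purity <- tibble::tibble(sample_id = bt1$sample_id,
                           purity = bt1$tumor_fraction)
  pr <- truth$proteins
  up <- pr$protein[pr$true_logfc > 0][1]
  alt <- alt_set(up, 1)
  res <- purity_association(mat[, bt1$sample_id], alt, purity)
  expect_equal(res$per_protein$rho, 1)       # zero noise: monotone in f
  expect_equal(res$aggregate$rho, 1)
  # constant purity errors
  expect_error(
    purity_association(mat[, bt1$sample_id], alt,
                       dplyr::mutate(purity, purity = 0.5)),
    "constant")
})

test_that("neutral proteins show no purity association beyond noise", {
  cfg <- sim_config(seed = 29)
  truth <- simulate_latent_profiles(cfg)
  mat <- tbl_to_matrix(latent_protein_matrix(truth, noise_sd = 0.2))
  bt <- truth$annotation[truth$annotation$collection_type == "BT", ] |>
    dplyr::left_join(truth$mixing, by = c("patient", "level"))
  purity <- tibble::tibble(sample_id = bt$sample_id,
                           purity = bt$tumor_fraction)
  pr <- truth$proteins
  neutral <- pr$protein[!pr$de][1:50]
  up <- pr$protein[pr$true_logfc > 0][1:20]
  alt <- alt_set(c(neutral, up), c(rep(1, 50), rep(1, 20)))
  res <- purity_association(mat[, bt$sample_id], alt, purity)
  rho_neutral <- res$per_protein$rho[res$per_protein$protein %in% neutral]
  rho_up <- res$per_protein$rho[res$per_protein$protein %in% up]
  # cross-patient pooled-reference scaling dilutes but never removes the
  # planted monotone relationship
  expect_lt(stats::median(abs(rho_neutral)), 0.35)
  expect_gt(stats::median(rho_up), 0.6)
  expect_gt(stats::median(rho_up), stats::median(abs(rho_neutral)) + 0.3)
})
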