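make_psms <- function(q, interf, ref, other) {
  tibble::tibble(
    plex_id = "plex_A",
    spectrum_id = sprintf("scan%03d", seq_along(q)),
    peptide = "PEPTIDE",
    protein_accession = sprintf("PROT%02d", seq_along(q)),
    q_value = q,
    isolation_interference_pct = interf,
    intensity_126 = ref,
    `intensity_127N` = other
  )
}

test_that("filter_psms applies each exclusion rule strictly", {
  # the 5-row worked example: q fail, interference fail, missing reference,
  # reference-only signal -> exactly 1 PSM survives
  psms <- make_psms(
    q = c(0.005, 0.02, 0.005, 0.005, 0.005),
    interf = c(10, 10, 60, 10, 10),
    ref = c(100, 100, 100, NA, 100),
    other = c(200, 200, 200, 200, NA)
  )
  kept <- filter_psms(psms)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$spectrum_id, "scan001")
  excl <- attr(kept, "exclusions")
  expect_equal(unname(excl["retained"]), 1L)
  expect_equal(sum(excl[setdiff(names(excl), "retained")]), 4L)

  # boundary values are excluded: interference exactly at 50, q exactly at 0.01
  boundary <- make_psms(q = c(0.005, 0.01), interf = c(50.0, 10),
                        ref = c(100, 100), other = c(50, 50))
  expect_equal(nrow(filter_psms(boundary)), 0L) |>
    suppressWarnings()
})

test_that("relaxing filter thresholds never shrinks the retained set", {
  co <- simulate_cohort(sim_config(n_patients = 2, n_proteins = 80,
                                   q_fail_frac = 0.2,
                                   interference_fail_frac = 0.2, seed = 6))
  grid_q <- c(0.005, 0.01, 0.05)
  grid_i <- c(30, 50, 80)
  last <- -1L
  for (i in seq_along(grid_q)) {
    n <- nrow(filter_psms(co$psms, q_max = grid_q[i],
                          interference_max = grid_i[i]))
    expect_gte(n, last)
    last <- n
  }
})

test_that("unknown reference channel and multi-accession rows are rejected", {
  psms <- make_psms(0.001, 1, 100, 200)
  expect_error(filter_psms(psms, reference_channel = "135N"), "unknown")
  psms$protein_accession[1] <- "P1;P2"
  expect_error(filter_psms(psms), "multiple accessions")
  kept <- filter_psms(psms, keep_first = TRUE)
  expect_equal(kept$protein_accession[1], "P1")
})

test_that("psm_ratios computes log2 ratios to the reference channel", {
  design <- tibble::tibble(
    plex_id = "plex_A", channel = c("126", "127N", "127C"),
    sample_id = c("pool", "s1", "s2"),
    is_reference = c(TRUE, FALSE, FALSE)
  )
  psms <- tibble::tibble(
    plex_id = "plex_A", spectrum_id = c("a", "b", "c"), peptide = "PEP",
    protein_accession = "P1", q_value = 0.001,
    isolation_interference_pct = 1,
    intensity_126 = c(100, 100, 100),
    `intensity_127N` = c(200, 100, 25),
    `intensity_127C` = c(NA, 100, 400)
  )
  r <- psm_ratios(psms, design)
  expect_equal(r$log2_ratio[r$spectrum_id == "a"], 1)      # log2(2)
  expect_equal(r$log2_ratio[r$spectrum_id == "b"], c(0, 0))
  expect_equal(sort(r$log2_ratio[r$spectrum_id == "c"]), c(-2, 2))
  expect_false("pool" %in% r$sample_id)
  # missing channel yields no row
  expect_equal(nrow(r[r$spectrum_id == "a", ]), 1L)
  # unfiltered zero reference is an error
  psms$intensity_126[1] <- 0
  expect_error(psm_ratios(psms, design), "filter_psms")
})

test_that("rollup takes per-sample medians and enforces min_psms per plex", {
  design <- tibble::tibble(
    plex_id = "plex_A", channel = c("126", "127N"),
    sample_id = c("pool", "s1"), is_reference = c(TRUE, FALSE)
  )
  ratios <- tibble::tibble(
    plex_id = "plex_A",
    spectrum_id = c("a", "b", "c", "d", "e", "f"),
    protein = c("P1", "P1", "P2", "P3", "P3", "P3"),
    sample_id = "s1",
    log2_ratio = c(0.4, 0.6, 5, 0, 1, 10)
  )
  out <- rollup_proteins(ratios, min_psms = 2)[["plex_A"]]
  expect_setequal(out$protein, c("P1", "P3"))   # P2 has a single PSM
  expect_equal(out$s1[out$protein == "P1"], 0.5)
  expect_equal(out$s1[out$protein == "P3"], 1)  # median robust to the outlier
  # PSM row order never matters
  shuffled <- ratios[c(4, 2, 6, 1, 5, 3), ]
  expect_equal(rollup_proteins(shuffled, min_psms = 2)[["plex_A"]], out)
})

test_that("normalize_medians centers columns and is idempotent", {
  m <- matrix(c(1, 2, 3, 0.2, 0.2, 5), 3, 2,
              dimnames = list(c("P1", "P2", "P3"), c("s1", "s2")))
  tbl <- matrix_to_tbl(m)
  out <- tbl_to_matrix(normalize_medians(tbl))
  expect_equal(unname(out[, "s1"]), c(-1, 0, 1))
  expect_equal(tbl_to_matrix(normalize_medians(normalize_medians(tbl))), out)
  # observed-value median with missing cells
  m2 <- matrix(c(0.2, 0.2, 5, NA), 4, 1,
               dimnames = list(paste0("P", 1:4), "s1"))
  out2 <- tbl_to_matrix(normalize_medians(matrix_to_tbl(m2)))
  expect_equal(unname(out2[, 1]), c(0, 0, 4.8, NA))
  # all-missing column errors with the sample named
  m3 <- matrix(NA_real_, 2, 1, dimnames = list(c("P1", "P2"), "bad_sample"))
  expect_error(normalize_medians(matrix_to_tbl(m3)), "bad_sample")
})

test_that("merge_plexes takes the protein union and rejects duplicates", {
  a <- matrix_to_tbl(matrix(1, 5, 2, dimnames = list(paste0("A", 1:5),
                                                     c("s1", "s2"))))
  b <- matrix_to_tbl(matrix(2, 7, 2, dimnames = list(paste0("B", 1:7),
                                                     c("s3", "s4"))))
  merged <- merge_plexes(list(a, b))
  expect_equal(nrow(merged), 12L)
  expect_true(all(is.na(tbl_to_matrix(merged)[paste0("A", 1:5),
                                              c("s3", "s4")])))
  # identical protein spaces leave no missingness
  b2 <- matrix_to_tbl(matrix(2, 5, 2, dimnames = list(paste0("A", 1:5),
                                                      c("s3", "s4"))))
  expect_false(anyNA(tbl_to_matrix(merge_plexes(list(a, b2)))))
  dup <- matrix_to_tbl(matrix(1, 2, 1, dimnames = list(c("C1", "C2"), "s1")))
  expect_error(merge_plexes(list(a, dup)), "duplicate sample id")
})

test_that("impute_knn drops under-quantified proteins and matches its contract", {
  m <- toy_matrix(10, 10, seed = 2)
  m[1, 1:6] <- NA          # observed in 40% of samples -> dropped
  m[2, 1] <- NA            # observed in 90% -> imputed
  out <- impute_knn(matrix_to_tbl(m), k = 3)
  expect_false("P001" %in% out$protein)
  expect_false(anyNA(tbl_to_matrix(out)))
  flags <- tbl_to_matrix(imputation_flags(out))
  expect_true(flags["P002", 1])
  expect_equal(sum(flags), 1)

  # k = 1 with an identical-profile neighbor copies its value
  m2 <- toy_matrix(5, 6, seed = 3)
  m2[2, ] <- m2[1, ]
  m2[1, 4] <- NA
  out2 <- tbl_to_matrix(impute_knn(matrix_to_tbl(m2), k = 1))
  expect_equal(out2["P001", 4], m2[2, 4])
})

test_that("impute_knn equals the exhaustive brute-force oracle", {
  set.seed(71)
  for (rep in 1:8) {
    n_p <- sample(8:30, 1)
    n_s <- sample(6:16, 1)
    m <- toy_matrix(n_p, n_s, seed = 100 + rep,
                    missing = floor(0.15 * n_p * n_s))
    keep <- rowMeans(!is.na(m)) >= 0.5
    m <- m[keep, , drop = FALSE]
    k <- sample(1:5, 1)
    got <- tbl_to_matrix(suppressWarnings(
      impute_knn(matrix_to_tbl(m), k = k, min_quant_frac = 0.5)))
    want <- oracle_knn_impute(m, k)
    expect_equal(got, want[rownames(got), , drop = FALSE], tolerance = 1e-12)
  }
})

test_that("zero-noise simulation round-trips through quantification exactly", {
  cfg <- sim_config(n_patients = 3, n_proteins = 120, noise_sd = 0,
                    frac_missing_per_plex = 0, q_fail_frac = 0,
                    interference_fail_frac = 0, frac_signal_missing = 0,
                    psm_count_dist = "constant", psms_per_protein = 3,
                    seed = 21)
  co <- simulate_cohort(cfg)
  q <- quantify_cohort(co$psms, co$design, co$annotation)
  got <- tbl_to_matrix(q$matrix)
  expect_false(any(as.matrix(imputation_flags(q$matrix)[, -1])))
  latent <- tbl_to_matrix(latent_protein_matrix(co$truth))
  latent <- sweep(latent, 2L, apply(latent, 2L, stats::median))
  expect_equal(got, latent[rownames(got), colnames(got)], tolerance = 1e-9)
})
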