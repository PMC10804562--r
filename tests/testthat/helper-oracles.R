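# Independent brute-force oracles used to verify the package's
# implementations. These are deliberately written as plain loops over the
# definitions, sharing no code with the package internals.

# k-NN imputation oracle: exhaustive distance computation per missing cell.
oracle_knn_impute <- function(m, k) {
  out <- m
  for (g in seq_len(nrow(m))) {
    for (s in seq_len(ncol(m))) {
      if (!is.na(m[g, s])) next
      cand <- c()
      dist <- c()
      for (h in seq_len(nrow(m))) {
        if (h == g || is.na(m[h, s])) next
        both <- !is.na(m[g, ]) & !is.na(m[h, ])
        if (!any(both)) next
        cand <- c(cand, h)
        dist <- c(dist, sqrt(sum((m[g, both] - m[h, both])^2)))
      }
      ord <- order(dist, rownames(m)[cand])
      use <- cand[ord][seq_len(min(k, length(cand)))]
      out[g, s] <- mean(m[use, s])
    }
  }
  out
}

# ssGSEA running-sum oracle for one sample vector.
oracle_ssgsea <- function(x, in_set, alpha) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  ord <- order(-x, names(x))
  num_in <- 0
  num_out <- 0
  total_w <- sum((r^alpha)[in_set])
  n_out <- sum(!in_set)
  score <- 0
  for (i in ord) {
    if (in_set[i]) num_in <- num_in + r[i]^alpha else num_out <- num_out + 1
    score <- score + num_in / total_w - num_out / n_out
  }
  unname(score)
}

# Exact two-sided Mann-Whitney p-value by enumeration of all rank
# assignments (no ties assumed).
oracle_mw_exact <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  u_all <- apply(combos, 2L, function(idx) {
    sum(rank(pooled)[idx]) - nx * (nx + 1) / 2
  })
  mu <- nx * ny / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Spearman rho from first principles (average ranks, Pearson on ranks).
oracle_spearman <- function(a, b) {
  ra <- rank(a)
  rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Small complete matrix with named rows/cols for quick tests.
toy_matrix <- function(n_prot, n_samp, seed = 1, missing = 0) {
  set.seed(seed)
  m <- matrix(rnorm(n_prot * n_samp), n_prot, n_samp,
              dimnames = list(sprintf("P%03d", seq_len(n_prot)),
                              sprintf("S%02d", seq_len(n_samp))))
  if (missing > 0) {
    idx <- sample.int(length(m), missing)
    m[idx] <- NA
  }
  m
}

# Minimal annotation for a matrix whose columns follow PTxx_TY_Lz naming.
annotation_from_names <- function(ids) {
  parts <- strsplit(ids, "_")
  tibble::tibble(
    sample_id = ids,
    patient = vapply(parts, `[`, "", 1L),
    collection_type = vapply(parts, `[`, "", 2L),
    level = as.integer(sub("^L", "", vapply(parts, `[`, "", 3L))),
    tumor_cellularity_pct = NA_real_
  )
}
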