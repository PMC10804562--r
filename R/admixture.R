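# ssGSEA tumor / stroma / immune admixture scoring and recovery of planted
# mixing fractions on synthetic bulk samples.

#' Single-sample GSEA scores
#'
#' Per sample, features are ranked by abundance (average ranks for ties;
#' the most abundant feature has rank N) and the ranked list is walked from
#' the top. The in-set running sum accumulates weights `rank^alpha`
#' (normalized to 1 over the set); the out-of-set running sum is the
#' unweighted ECDF of out-of-set features. The score is the sum of the
#' running differences over all list positions — the classic single-sample
#' enrichment statistic. Scores are rank-based, hence invariant under
#' strictly monotone transforms of a sample's abundances.
#'
#' @param tbl Complete wide matrix tibble or matrix.
#' @param signatures Named list of feature-id vectors (e.g. from
#'   [read_gmt()] or [truth_signatures()]).
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize Min-max normalize each signature's scores across
#'   samples (default FALSE: raw running sums).
#' @return Long tibble (sample_id, signature, score) of class
#'   `lmd_scores`, with a `"coverage"` attribute giving the fraction of
#'   each signature found in the matrix.
#' @examples
#' co <- simulate_cohort(sim_config(n_patients = 2, n_proteins = 60, seed = 8))
#' mat <- latent_protein_matrix(co$truth)
#' sc <- ssgsea_score(mat, truth_signatures(co$truth, n_per_set = 10))
#' head(sc)
#' @export
ssgsea_score <- function(tbl, signatures, alpha = 0.25, normalize = FALSE) {
  m <- as_protein_matrix(tbl)
  if (anyNA(m)) stop("matrix must be complete (impute first)", call. = FALSE)
  stopifnot(is.list(signatures), length(signatures) > 0,
            !is.null(names(signatures)))
  n <- nrow(m)
  feats <- rownames(m)
  sets <- lapply(names(signatures), function(nm) {
    sig <- signatures[[nm]]
    if (length(sig) == 0L) {
      stop(sprintf("signature '%s' is empty", nm), call. = FALSE)
    }
    hit <- feats %in% sig
    if (!any(hit)) {
      stop(sprintf("signature '%s' shares no features with the matrix", nm),
           call. = FALSE)
    }
    hit
  })
  names(sets) <- names(signatures)
  coverage <- tibble::tibble(
    signature = names(signatures),
    n_set = unname(lengths(signatures)),
    n_matched = unname(vapply(sets, sum, integer(1)))
  ) |>
    dplyr::mutate(coverage = .data$n_matched / .data$n_set)

  res <- matrix(NA_real_, ncol(m), length(sets),
                dimnames = list(colnames(m), names(sets)))
  for (s in seq_len(ncol(m))) {
    x <- m[, s]
    r <- rank(x, ties.method = "average")       # top feature ~ rank n
    ord <- order(-x, feats)                     # descending; ties by id
    w <- r^alpha
    for (j in seq_along(sets)) {
      hit <- sets[[j]][ord]
      p_in <- cumsum(w[ord] * hit) / sum(w[ord][hit])
      p_out <- cumsum(!hit) / sum(!hit)
      res[s, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    res <- apply(res, 2L, function(v) {
      rng <- range(v)
      if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
    })
  }
  out <- tibble::as_tibble(res, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "signature",
                        values_to = "score")
  attr(out, "coverage") <- coverage
  class(out) <- c("lmd_scores", class(out))
  out
}

#' Ground-truth tumor / stroma signatures for synthetic cohorts
#'
#' Builds the default signature sets for simulated data from the planted
#' fold changes: the `n_per_set` proteins most elevated in ET form the
#' Tumor signature, the most elevated in ES the Stroma signature. Immune
#' admixture is not planted by the simulator, so no Immune set is built;
#' supply real signatures via GMT for that.
#'
#' @param truth An `lmd_truth`.
#' @param n_per_set Proteins per signature (default 50).
#' @return Named list with `Tumor` and `Stroma` character vectors.
#' @export
truth_signatures <- function(truth, n_per_set = 50L) {
  stopifnot(inherits(truth, "lmd_truth"))
  pr <- truth$proteins
  up <- pr[order(-pr$true_logfc, pr$protein), ]
  dn <- pr[order(pr$true_logfc, pr$protein), ]
  n_up <- min(n_per_set, sum(pr$true_logfc > 0))
  n_dn <- min(n_per_set, sum(pr$true_logfc < 0))
  if (n_up == 0L || n_dn == 0L) {
    stop("ground truth has no planted effects in one direction", call. = FALSE)
  }
  list(Tumor = up$protein[seq_len(n_up)], Stroma = dn$protein[seq_len(n_dn)])
}

#' Recovery of planted mixing fractions from admixture scores
#'
#' Spearman correlation between a signature's score and the true stroma
#' fraction (`1 - tumor fraction`) over the simulated BT samples.
#'
#' @param scores An `lmd_scores` tibble from [ssgsea_score()].
#' @param truth An `lmd_truth` (supplies mixing fractions and annotation).
#' @param signature Signature name to evaluate (default `"Stroma"`).
#' @return List with `rho`, `p_value`, and `data` (sample_id, score,
#'   stroma_fraction).
#' @export
purity_recovery <- function(scores, truth, signature = "Stroma") {
  stopifnot(inherits(truth, "lmd_truth"))
  bt <- truth$annotation[truth$annotation$collection_type == "BT", ,
                         drop = FALSE] |>
    dplyr::left_join(truth$mixing, by = c("patient", "level")) |>
    dplyr::mutate(stroma_fraction = 1 - .data$tumor_fraction)
  sc <- scores[scores$signature == signature, , drop = FALSE]
  dat <- dplyr::inner_join(
    bt[, c("sample_id", "stroma_fraction")], sc[, c("sample_id", "score")],
    by = "sample_id"
  )
  if (nrow(dat) < 3L) {
    stop("need at least 3 BT samples with scores and ground truth",
         call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(dat$score, dat$stroma_fraction, method = "spearman")
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, data = dat)
}
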