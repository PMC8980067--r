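#' Squared LD correlation between two dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete subjects; defined as 0
#' when either variant has zero variance on the complete pairs.
#'
#' @param dosage_i,dosage_j Dosage vectors.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(dosage_i, dosage_j) {
  ok <- !is.na(dosage_i) & !is.na(dosage_j)
  if (sum(ok) < 2) return(0)
  x <- dosage_i[ok]; y <- dosage_j[ok]
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)^2
}

#' Greedy window LD pruning
#'
#' PLINK-style `indep-pairwise` pruning: within a sliding window of
#' `window` variants (stepped by `step`), the later variant of any pair with
#' r-squared at or above `r2_threshold` is removed. Yields the approximately
#' independent marker set used for relatedness estimation.
#'
#' @param geno A [geno_matrix()].
#' @param r2_threshold Removal threshold (default 0.2).
#' @param window,step Window size and step in variant counts (defaults 50, 5).
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(geno, r2_threshold = 0.2, window = 50, step = 5) {
  m <- ncol(geno$dosage)
  keep <- rep(TRUE, m)
  start <- 1
  while (start <= m) {
    idx <- seq(start, min(start + window - 1, m))
    idx <- idx[keep[idx]]
    if (length(idx) > 1) {
      for (a in seq_along(idx)[-length(idx)]) {
        if (!keep[idx[a]]) next
        for (b in seq((a + 1), length(idx))) {
          if (!keep[idx[b]]) next
          if (geno$variants$chrom[idx[a]] != geno$variants$chrom[idx[b]]) next
          if (ld_r2(geno$dosage[, idx[a]], geno$dosage[, idx[b]]) >= r2_threshold) {
            keep[idx[b]] <- FALSE
          }
        }
      }
    }
    if (start + window - 1 >= m) break
    start <- start + step
  }
  geno$variants$id[keep]
}

#' Identity-by-descent relatedness (method of moments)
#'
#' PLINK-style moment estimator: per-pair identity-by-state (IBS) counts over
#' shared non-missing variants are combined with allele-frequency-based
#' expected IBS probabilities under IBD states 0/1/2 to solve for
#' P(IBD = 0, 1, 2); estimates are clipped to \[0, 1\] and renormalized, and
#' `pi_hat = P(IBD=1)/2 + P(IBD=2)`.
#'
#' @param geno A [geno_matrix()].
#' @param variant_ids Approximately independent variants to use (e.g. from
#'   [ld_prune()]); defaults to all variants.
#' @param min_informative Pairs with fewer shared informative variants are
#'   flagged `low_informative` with a warning (default 50).
#' @return Tibble with one row per unordered subject pair: `id1`, `id2`,
#'   `ibs0`, `ibs1`, `ibs2`, `k0`, `k1`, `k2`, `pi_hat`, `n_used`,
#'   `low_informative`.
#' @export
ibd_estimate <- function(geno, variant_ids = NULL, min_informative = 50) {
  d <- geno$dosage
  if (!is.null(variant_ids)) d <- d[, variant_ids, drop = FALSE]
  n <- nrow(d)
  if (n < 2) stop("need at least two subjects", call. = FALSE)

  called <- !is.na(d)
  af <- colSums(d, na.rm = TRUE) / (2 * colSums(called))
  poly <- is.finite(af) & af > 0 & af < 1
  d <- d[, poly, drop = FALSE]
  called <- called[, poly, drop = FALSE]
  p <- af[poly]; q <- 1 - p

  # per-variant expected IBS probabilities under each IBD state
  e_ibs0_k0 <- 2 * p^2 * q^2
  e_ibs1_k0 <- 4 * p^3 * q + 4 * p * q^3
  e_ibs2_k0 <- 1 - e_ibs0_k0 - e_ibs1_k0
  e_ibs1_k1 <- 2 * p^2 * q + 2 * p * q^2
  e_ibs2_k1 <- 1 - e_ibs1_k1
  m_poly <- ncol(d)
  E00 <- sum(e_ibs0_k0); E10 <- sum(e_ibs1_k0); E20 <- sum(e_ibs2_k0)
  E11 <- sum(e_ibs1_k1); E21 <- sum(e_ibs2_k1)

  # pairwise IBS via indicator cross-products (0 where either call missing)
  A0 <- (called & d == 0) + 0; A1 <- (called & d == 1) + 0
  A2 <- (called & d == 2) + 0
  A0[is.na(A0)] <- 0; A1[is.na(A1)] <- 0; A2[is.na(A2)] <- 0
  IBS0 <- A0 %*% t(A2); IBS0 <- IBS0 + t(IBS0)
  IBS2 <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)
  NM <- (called + 0) %*% t(called + 0)
  IBS1 <- NM - IBS0 - IBS2

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    used <- NM[i, j]
    s <- used / m_poly  # scale expectations to the shared variant set
    k0 <- if (E00 > 0) IBS0[i, j] / (E00 * s) else 0
    k1 <- if (E11 > 0) (IBS1[i, j] - k0 * E10 * s) / (E11 * s) else 0
    k2 <- (IBS2[i, j] - k0 * E20 * s - k1 * E21 * s) / used
    k <- pmin(pmax(c(k0, k1, k2), 0), 1)
    if (sum(k) > 0) k <- k / sum(k)
    tibble(
      id1 = rownames(d)[i], id2 = rownames(d)[j],
      ibs0 = IBS0[i, j], ibs1 = IBS1[i, j], ibs2 = IBS2[i, j],
      k0 = k[1], k1 = k[2], k2 = k[3],
      pi_hat = pmin(pmax(k[2] / 2 + k[3], 0), 1),
      n_used = used,
      low_informative = used < min_informative
    )
  })
  if (any(res$low_informative)) {
    warning(sprintf("%d pair(s) estimated from fewer than %d informative variants",
                    sum(res$low_informative), min_informative), call. = FALSE)
  }
  res
}
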