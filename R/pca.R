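#' Principal components of the genotype matrix
#'
#' PCs of the column-standardized dosage matrix (missing calls mean-imputed;
#' monomorphic variants contribute zero after centering). Component signs are
#' fixed so the loading of largest magnitude is positive, making the result
#' deterministic.
#'
#' @param geno A [geno_matrix()] (normally QC-passed).
#' @param k Number of components; truncated to the matrix rank with a warning
#'   when larger.
#' @return Tibble `subject_id`, `PC1` ... `PCk`, with attributes
#'   `var_explained` (proportion per component) and `rotation`.
#' @export
genotype_pca <- function(geno, k = 10) {
  x <- geno$dosage
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  x <- scale(x)
  sds <- attr(x, "scaled:scale")
  x[, sds == 0 | !is.finite(sds)] <- 0

  rank_max <- min(nrow(x) - 1, ncol(x))
  if (k > rank_max) {
    warning(sprintf("k = %d exceeds the matrix rank; truncated to %d", k, rank_max),
            call. = FALSE)
    k <- rank_max
  }
  sv <- svd(x, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    load <- sv$v[, j]
    sign(load[which.max(abs(load))])
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k, k), 2, flip, `*`)
  rotation <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, `*`)
  colnames(scores) <- colnames(rotation) <- paste0("PC", seq_len(k))

  out <- dplyr::bind_cols(tibble(subject_id = subject_ids(geno)),
                          as_tibble(scores))
  attr(out, "var_explained") <- sv$d[seq_len(k)]^2 / sum(x^2)
  attr(out, "rotation") <- rotation
  out
}
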