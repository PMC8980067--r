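#' Methylation probe quality control
#'
#' Removes a probe when (1) its detection p-value is at or above
#' `detection_p_max` in more than `detection_fail_frac` of samples, (2) its
#' bead count is below `bead_min` in at least `bead_fail_frac` of samples, or
#' (3) it carries a SNP at the CpG interrogation or single-base-extension
#' site. Criteria whose input matrix is absent are skipped with a warning.
#' The three rules are independent per probe, so the surviving set does not
#' depend on the order in which they are applied.
#'
#' @param meth A [meth_matrix()].
#' @param detection_p_max Per-call detection-p failure threshold (default 0.01).
#' @param detection_fail_frac Maximum tolerated fraction of failed samples
#'   (default 0.01).
#' @param bead_min Minimum bead count (default 3).
#' @param bead_fail_frac Failure fraction at which the bead rule removes a
#'   probe (default 0.05).
#' @param drop_snp_overlap Apply the SNP-overlap rule (default TRUE).
#' @return List with `methylation` (filtered [meth_matrix()]) and `report`
#'   (per-probe tibble of criteria plus per-criterion removal counts).
#' @export
probe_qc <- function(meth,
                     detection_p_max = 0.01,
                     detection_fail_frac = 0.01,
                     bead_min = 3,
                     bead_fail_frac = 0.05,
                     drop_snp_overlap = TRUE) {
  m <- ncol(meth$beta)
  if (is.null(meth$detection_p)) {
    warning("no detection-p matrix supplied; detection criterion skipped",
            call. = FALSE)
    fail_det <- rep(FALSE, m)
  } else {
    fail_det <- colMeans(meth$detection_p >= detection_p_max) > detection_fail_frac
  }
  if (is.null(meth$bead_count)) {
    warning("no bead-count matrix supplied; bead criterion skipped",
            call. = FALSE)
    fail_bead <- rep(FALSE, m)
  } else {
    fail_bead <- colMeans(meth$bead_count < bead_min) >= bead_fail_frac
  }
  fail_snp <- if (drop_snp_overlap) meth$probes$snp_overlap else rep(FALSE, m)

  report <- tibble(
    probe_id = meth$probes$probe_id,
    fail_detection = unname(fail_det),
    fail_bead = unname(fail_bead),
    fail_snp_overlap = unname(fail_snp),
    pass = unname(!(fail_det | fail_bead | fail_snp))
  )
  keep <- which(report$pass)
  if (length(keep) == 0) stop("no probes pass QC", call. = FALSE)
  list(
    methylation = subset_meth(meth, probes = keep),
    report = report,
    n_removed = c(detection = sum(fail_det), bead = sum(fail_bead),
                  snp_overlap = sum(fail_snp), total = m - length(keep))
  )
}

#' Methylation sample outlier detection on principal components
#'
#' Flags subjects whose coordinate on any of the first `k` beta-value
#' principal components lies more than `sd_limit` standard deviations from
#' the component mean.
#'
#' @param meth A [meth_matrix()].
#' @param k Number of components (default 2).
#' @param sd_limit Flagging limit in SD units (default 4).
#' @return Tibble `subject_id`, `PC1..PCk`, `outlier`.
#' @export
sample_qc_pca <- function(meth, k = 2, sd_limit = 4) {
  if (nrow(meth$beta) < 3) stop("need at least 3 subjects", call. = FALSE)
  k <- min(k, nrow(meth$beta) - 1, ncol(meth$beta))
  pc <- prcomp(meth$beta, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  z <- scale(scores)
  out <- rowSums(abs(z) > sd_limit, na.rm = TRUE) > 0
  dplyr::bind_cols(
    tibble(subject_id = rownames(meth$beta)),
    as_tibble(scores),
    tibble(outlier = unname(out))
  )
}
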