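#' Genotype quality control
#'
#' Applies the standard SNP-array filters: an optional per-call quality mask
#' (calls with GenCall-like score below `gencall_min` are set missing before
#' any rate is computed), then per-variant call rate, minor-allele frequency
#' and exact Hardy-Weinberg filters, then a per-subject call-rate filter
#' computed on the passing variants. Every decision is recorded in the report.
#'
#' @param geno A [geno_matrix()].
#' @param call_rate_min Minimum per-variant call rate (default 0.95).
#' @param maf_min Minimum minor-allele frequency (default 0.01).
#' @param hwe_min_p Minimum exact HWE p-value (default 1e-6).
#' @param gencall_min Per-call quality threshold (default 0.2); applied only
#'   when the genotype matrix carries a quality matrix.
#' @param subject_call_rate_min Minimum per-subject call rate (default 0.95).
#' @return A list with `genotypes` (filtered [geno_matrix()]) and `report`
#'   (list of tibbles `variants`, `subjects`, plus `thresholds` and counts).
#' @export
snp_qc <- function(geno,
                   call_rate_min = 0.95,
                   maf_min = 0.01,
                   hwe_min_p = 1e-6,
                   gencall_min = 0.2,
                   subject_call_rate_min = 0.95) {
  d <- geno$dosage
  n_masked <- 0L
  if (!is.null(geno$quality)) {
    mask <- !is.na(geno$quality) & geno$quality < gencall_min
    n_masked <- sum(mask & !is.na(d))
    d[mask] <- NA
  }

  n_called <- colSums(!is.na(d))
  call_rate <- n_called / nrow(d)
  alt_count <- colSums(d, na.rm = TRUE)
  af <- ifelse(n_called > 0, alt_count / (2 * n_called), NA_real_)
  maf <- pmin(af, 1 - af)

  n_aa <- colSums(d == 2, na.rm = TRUE)   # ALT hom
  n_Aa <- colSums(d == 1, na.rm = TRUE)
  n_AA <- colSums(d == 0, na.rm = TRUE)
  hwe_p <- hwe_exact_p(n_AA, n_Aa, n_aa)

  variant_report <- tibble(
    id = geno$variants$id,
    call_rate = unname(call_rate),
    maf = unname(maf),
    hwe_p = unname(hwe_p),
    pass_call_rate = unname(call_rate >= call_rate_min),
    pass_maf = unname(!is.na(maf) & maf >= maf_min),
    pass_hwe = unname(!is.na(hwe_p) & hwe_p >= hwe_min_p)
  )
  variant_report$pass <- variant_report$pass_call_rate &
    variant_report$pass_maf & variant_report$pass_hwe

  keep_v <- which(variant_report$pass)
  if (length(keep_v) == 0) {
    stop("no variants pass QC; nothing left to analyse", call. = FALSE)
  }

  d_kept <- d[, keep_v, drop = FALSE]
  subj_rate <- rowMeans(!is.na(d_kept))
  subject_report <- tibble(
    subject_id = rownames(d),
    call_rate = subj_rate,
    pass = subj_rate >= subject_call_rate_min
  )
  keep_s <- which(subject_report$pass)
  if (length(keep_s) == 0) {
    stop("no subjects pass QC; nothing left to analyse", call. = FALSE)
  }

  filtered <- geno_matrix(
    d[keep_s, keep_v, drop = FALSE],
    geno$variants[keep_v, , drop = FALSE],
    quality = if (is.null(geno$quality)) NULL
              else geno$quality[keep_s, keep_v, drop = FALSE]
  )
  list(
    genotypes = filtered,
    report = list(
      variants = variant_report,
      subjects = subject_report,
      thresholds = list(call_rate_min = call_rate_min, maf_min = maf_min,
                        hwe_min_p = hwe_min_p, gencall_min = gencall_min,
                        subject_call_rate_min = subject_call_rate_min),
      n_calls_masked = n_masked,
      n_variants_removed = sum(!variant_report$pass),
      n_subjects_removed = sum(!subject_report$pass)
    )
  )
}
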