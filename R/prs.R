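#' Align GWAS effect alleles to the counted (ALT) allele
#'
#' For each variant shared between the GWAS summary and the genotype records:
#' if the effect allele is the counted allele the weight applies to the dosage
#' as-is; if it is the other allele the score uses `2 - dosage` (recorded as
#' `flip = TRUE`). Strand-ambiguous pairs (A/T, C/G) are dropped by default,
#' and allele-set mismatches are always dropped; drops are reported, not fatal.
#'
#' @param gwas GWAS summary tibble.
#' @param variants Variant tibble from a [geno_matrix()].
#' @param drop_ambiguous Drop strand-ambiguous variants (default TRUE).
#' @return Tibble `id`, `weight`, `flip`, `status` where `status` is one of
#'   `"ok"`, `"ambiguous"`, `"mismatch"`; only `"ok"` rows enter scoring.
#' @export
align_alleles <- function(gwas, variants, drop_ambiguous = TRUE) {
  x <- dplyr::inner_join(gwas, variants[, c("id", "ref", "alt")], by = "id")
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ambiguous <- x$other_allele == comp[x$effect_allele]
  match_fwd <- x$effect_allele == x$alt & x$other_allele == x$ref
  match_rev <- x$effect_allele == x$ref & x$other_allele == x$alt
  status <- dplyr::case_when(
    drop_ambiguous & ambiguous ~ "ambiguous",
    match_fwd | match_rev ~ "ok",
    TRUE ~ "mismatch"
  )
  n_drop <- sum(status != "ok")
  if (n_drop > 0) {
    message(sprintf("align_alleles: dropped %d variant(s) (%d ambiguous, %d mismatched)",
                    n_drop, sum(status == "ambiguous"), sum(status == "mismatch")))
  }
  tibble(id = x$id, weight = x$weight, flip = match_rev, status = status)
}

#' Compute a polygenic risk score at a p-value threshold
#'
#' `score_subject = sum over clumped, aligned variants with GWAS p <= p_T of
#' weight x aligned dosage` (aligned dosage counts the effect allele). Missing
#' dosages are imputed as twice the effect-allele frequency observed in the
#' cohort.
#'
#' @param geno A [geno_matrix()].
#' @param gwas GWAS summary tibble.
#' @param clumped_ids Variant ids retained by [greedy_clump()].
#' @param p_threshold GWAS p-value cutoff `p_T`.
#' @param aligned Optional precomputed [align_alleles()] result.
#' @return A `prs_result`: list with `scores` (tibble `subject_id`, `score`),
#'   `p_threshold`, `variant_ids`, `weights`, `scan` (NULL here; filled by
#'   [optimize_threshold()]).
#' @export
compute_prs <- function(geno, gwas, clumped_ids, p_threshold, aligned = NULL) {
  if (is.null(aligned)) aligned <- align_alleles(gwas, geno$variants)
  ok <- aligned[aligned$status == "ok", ]
  pmap <- setNames(gwas$p_value, gwas$id)
  use <- ok[ok$id %in% clumped_ids & pmap[ok$id] <= p_threshold, ]
  sid <- subject_ids(geno)
  if (nrow(use) == 0) {
    warning(sprintf("no variants selected at p_T = %g; all scores are 0",
                    p_threshold), call. = FALSE)
    return(new_prs_result(tibble(subject_id = sid, score = 0),
                          p_threshold, character(0), numeric(0)))
  }
  d <- geno$dosage[, use$id, drop = FALSE]
  d[, use$flip] <- 2 - d[, use$flip, drop = FALSE]
  if (anyNA(d)) {
    eaf <- colMeans(d, na.rm = TRUE) / 2
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- 2 * eaf[idx[, 2]]
  }
  score <- as.numeric(d %*% use$weight)
  new_prs_result(tibble(subject_id = sid, score = score),
                 p_threshold, use$id, setNames(use$weight, use$id))
}

new_prs_result <- function(scores, p_threshold, variant_ids, weights,
                           scan = NULL) {
  structure(
    list(scores = scores, p_threshold = p_threshold,
         variant_ids = variant_ids, weights = weights, scan = scan),
    class = "prs_result"
  )
}

#' @export
print.prs_result <- function(x, ...) {
  cat(sprintf("<prs_result> p_T = %g, %d variants, %d subjects%s\n",
              x$p_threshold, length(x$variant_ids), nrow(x$scores),
              if (is.null(x$scan)) "" else
                sprintf(" (selected from a %d-threshold scan)", nrow(x$scan))))
  invisible(x)
}

#' @export
tidy.prs_result <- function(x, ...) x$scores

#' @export
glance.prs_result <- function(x, ...) {
  tibble(p_threshold = x$p_threshold, n_variants = length(x$variant_ids),
         n_subjects = nrow(x$scores),
         scan_thresholds = if (is.null(x$scan)) 0L else nrow(x$scan))
}

#' Select the maximally informative PRS p-value threshold
#'
#' Computes the PRS at every threshold of the grid (default 0.01 to 0.50 in
#' steps of 0.01), fits a logistic regression of family-history status on each
#' score, and selects the threshold with the smallest two-sided Wald p-value
#' on the PRS coefficient; ties break toward the smaller threshold.
#' Thresholds whose logistic fit does not converge (e.g. separation) are
#' flagged and excluded from selection. The full scan table is retained.
#'
#' @param geno A [geno_matrix()].
#' @param gwas GWAS summary tibble.
#' @param clumped_ids Variant ids retained by [greedy_clump()].
#' @param family_history Binary (0/1 or two-level) vector, one per subject.
#' @param grid Threshold grid (default `seq(0.01, 0.5, by = 0.01)`).
#' @return A `prs_result` at the selected threshold, with the scan table
#'   (`p_threshold`, `n_variants`, `beta`, `se`, `p`, `converged`) attached.
#' @export
optimize_threshold <- function(geno, gwas, clumped_ids, family_history,
                               grid = seq(0.01, 0.5, by = 0.01)) {
  fh <- as_binary_numeric(family_history, "family_history")
  if (length(fh) != nrow(geno$dosage)) {
    stop("family_history must have one value per subject", call. = FALSE)
  }
  if (length(unique(na.omit(fh))) < 2) {
    stop("both family-history classes must be non-empty", call. = FALSE)
  }
  aligned <- align_alleles(gwas, geno$variants)
  scan <- purrr::map_dfr(grid, function(pt) {
    prs <- suppressWarnings(compute_prs(geno, gwas, clumped_ids, pt, aligned))
    s <- prs$scores$score
    if (sd(s) == 0) {
      return(tibble(p_threshold = pt, n_variants = length(prs$variant_ids),
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    converged = FALSE))
    }
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(fh ~ s, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    cf <- summary(fit)$coefficients
    conv <- fit$converged && !sep && "s" %in% rownames(cf)
    tibble(p_threshold = pt, n_variants = length(prs$variant_ids),
           beta = if (conv) cf["s", 1] else NA_real_,
           se = if (conv) cf["s", 2] else NA_real_,
           p = if (conv) cf["s", 4] else NA_real_,
           converged = conv)
  })
  usable <- scan[scan$converged & !is.na(scan$p), ]
  if (nrow(usable) == 0) {
    stop("no threshold produced a converged logistic fit", call. = FALSE)
  }
  best_pt <- usable$p_threshold[order(usable$p, usable$p_threshold)][1]
  best <- suppressWarnings(compute_prs(geno, gwas, clumped_ids, best_pt, aligned))
  best$scan <- scan
  best
}
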