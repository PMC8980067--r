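#' Greedy LD clumping of GWAS variants
#'
#' Iterates variants shared between the GWAS summary and the genotype matrix
#' in order of ascending GWAS p-value (ties broken by chromosome, then
#' position); a variant is kept unless it lies within `window_kb` of an
#' already-kept variant on the same chromosome with squared dosage
#' correlation at or above `r2_threshold`. Performed once on the full summary
#' set so p-value-threshold subsets of the result are nested.
#'
#' @param gwas GWAS summary tibble (see [read_gwas()]).
#' @param geno A [geno_matrix()].
#' @param r2_threshold Clumping r-squared (default 0.1, the PRS-convention
#'   default).
#' @param window_kb Clumping window in kilobases (default 250).
#' @return Character vector of retained (index) variant ids.
#' @export
greedy_clump <- function(gwas, geno, r2_threshold = 0.1, window_kb = 250) {
  shared <- dplyr::inner_join(
    gwas,
    geno$variants[, c("id", "chrom", "pos")],
    by = "id", suffix = c("", ".geno")
  )
  # coordinates follow the genotype records
  if ("chrom.geno" %in% names(shared)) {
    shared$chrom <- shared$chrom.geno
    shared$pos <- shared$pos.geno
  }
  shared <- shared[order(shared$p_value, shared$chrom, shared$pos), ]
  if (nrow(shared) == 0) return(character(0))

  col_of <- match(shared$id, geno$variants$id)
  kept <- integer(0)
  for (r in seq_len(nrow(shared))) {
    ok <- TRUE
    if (length(kept) > 0) {
      near <- kept[shared$chrom[kept] == shared$chrom[r] &
                     abs(shared$pos[kept] - shared$pos[r]) <= window_kb * 1000]
      for (k in near) {
        if (ld_r2(geno$dosage[, col_of[r]], geno$dosage[, col_of[k]]) >=
            r2_threshold) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) kept <- c(kept, r)
  }
  shared$id[kept]
}
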