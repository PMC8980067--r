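#' Cis-meQTL scan for selected probes
#'
#' For each probe, regresses its M-value on the dosage of every variant lying
#' within `window_kb` of the probe on the same chromosome (simple linear
#' regression over pairwise-complete subjects), and reports the slope, its
#' two-sided p-value and Storey q-values computed across all tested pairs.
#'
#' @param m_matrix M-value matrix (subjects x probes); row names must match
#'   the genotype subject ids.
#' @param geno A [geno_matrix()].
#' @param probes Probe annotation tibble (`probe_id`, `chrom`, `pos`) covering
#'   the scanned probes.
#' @param probe_ids Probes to scan (default: all columns of `m_matrix`).
#' @param window_kb Cis window in kilobases (default 500).
#' @return Tibble `probe_id`, `variant_id`, `n`, `beta`, `se`, `p`, `q`;
#'   empty (zero rows) when no variant falls in any window.
#' @export
meqtl_scan <- function(m_matrix, geno, probes, probe_ids = NULL,
                       window_kb = 500) {
  m <- as.matrix(m_matrix)
  if (is.null(probe_ids)) probe_ids <- colnames(m)
  shared <- intersect(rownames(m), subject_ids(geno))
  if (length(shared) < 3) stop("fewer than 3 shared subjects", call. = FALSE)
  m <- m[shared, , drop = FALSE]
  d_all <- geno$dosage[shared, , drop = FALSE]
  probes <- as_tibble(probes)
  validate_table(probes, c("probe_id", "chrom", "pos"), "probes")

  rows <- purrr::map_dfr(probe_ids, function(pid) {
    pr <- probes[probes$probe_id == pid, ]
    if (nrow(pr) == 0) stop(sprintf("probe %s has no annotation", pid),
                            call. = FALSE)
    cand <- which(geno$variants$chrom == pr$chrom[1] &
                    abs(geno$variants$pos - pr$pos[1]) <= window_kb * 1000)
    if (length(cand) == 0) return(tibble())
    purrr::map_dfr(cand, function(vi) {
      x <- d_all[, vi]
      y <- m[, pid]
      ok <- !is.na(x) & !is.na(y)
      nn <- sum(ok)
      if (nn < 3 || sd(x[ok]) == 0) {
        return(tibble(probe_id = pid, variant_id = geno$variants$id[vi],
                      n = nn, beta = NA_real_, se = NA_real_, p = NA_real_))
      }
      xs <- x[ok]; ys <- y[ok]
      sxx <- sum((xs - mean(xs))^2)
      b <- sum((xs - mean(xs)) * (ys - mean(ys))) / sxx
      res <- ys - mean(ys) - b * (xs - mean(xs))
      se <- sqrt(sum(res^2) / (nn - 2) / sxx)
      tstat <- b / se
      tibble(probe_id = pid, variant_id = geno$variants$id[vi],
             n = nn, beta = b, se = se, p = 2 * pt(-abs(tstat), nn - 2))
    })
  })
  if (nrow(rows) == 0) {
    return(tibble(probe_id = character(0), variant_id = character(0),
                  n = integer(0), beta = numeric(0), se = numeric(0),
                  p = numeric(0), q = numeric(0)))
  }
  rows$q <- NA_real_
  tested <- !is.na(rows$p)
  if (any(tested)) {
    rows$q[tested] <- suppressWarnings(storey_qvalues(rows$p[tested]))
  }
  rows
}
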