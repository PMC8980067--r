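# Independent oracles and small in-code fixtures shared across the suite.

# Exact HWE p-value by direct log-multinomial enumeration over the
# heterozygote-count support (independent of the package's ratio recurrence).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa
  h <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  logp <- lchoose(n, (na - h) / 2) + lchoose(n - (na - h) / 2, h) +
    h * log(2) - lchoose(2 * n, na)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, h)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# Brute-force Benjamini-Hochberg: q_i = min over j with p_j >= p_i of
# m * p_j / rank(p_j), by explicit search.
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    j <- which(p >= p[i])
    min(pmin(m * p[j] / r[j], 1))
  }, numeric(1))
}

# Brute-force order-respecting clumping re-implementation.
clump_oracle <- function(gwas, geno, r2_threshold, window_kb) {
  v <- geno$variants
  tab <- merge(as.data.frame(gwas), as.data.frame(v[, c("id", "chrom", "pos")]),
               by = "id", suffixes = c("_gwas", ""))
  if (!"chrom" %in% names(tab)) names(tab)[names(tab) == "chrom_gwas"] <- "chrom"
  tab <- tab[order(tab$p_value, tab$chrom, tab$pos), ]
  kept <- character(0)
  for (i in seq_len(nrow(tab))) {
    excl <- FALSE
    for (k in kept) {
      krow <- tab[tab$id == k, ]
      if (krow$chrom == tab$chrom[i] &&
          abs(krow$pos - tab$pos[i]) <= window_kb * 1000) {
        x <- geno$dosage[, tab$id[i]]
        y <- geno$dosage[, k]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) >= 2 && sd(x[ok]) > 0 && sd(y[ok]) > 0 &&
            cor(x[ok], y[ok])^2 >= r2_threshold) {
          excl <- TRUE
          break
        }
      }
    }
    if (!excl) kept <- c(kept, tab$id[i])
  }
  kept
}

# Small deterministic genotype fixture with hand-controllable dosages.
make_geno_fixture <- function(dosage, chrom = NULL, pos = NULL,
                              ref = NULL, alt = NULL) {
  m <- ncol(dosage)
  variants <- tibble::tibble(
    id = colnames(dosage) %||% sprintf("v%03d", seq_len(m)),
    chrom = chrom %||% rep(1L, m),
    pos = pos %||% (1000L * seq_len(m)),
    ref = ref %||% rep("A", m),
    alt = alt %||% rep("C", m)
  )
  colnames(dosage) <- variants$id
  geno_matrix(dosage, variants)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Covariate frame of the kind the association models expect.
make_covariates <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    age = runif(n, 15, 30),
    gender = sample(c("Female", "Male"), n, replace = TRUE),
    race = sample(c("Caucasian", "African American"), n, replace = TRUE),
    smoking = sample(c("No", "Yes", "Unknown"), n, replace = TRUE)
  ))
}

# Null brain-measure generator used by FDR / type-I simulations: a sim_config
# with every planted effect switched off.
null_sim_config <- function(n, n_measures, seed, ...) {
  sim_config(n_subjects = n, n_bds = max(1, floor(n / 2)), n_snps = 10,
             n_probes = 10, n_signal_probes = 0, n_causal_snps = 0,
             n_measures = n_measures, n_affected_measures = 0, seed = seed, ...)
}

null_truth <- function(n_measures) {
  list(true_effects = tibble::tibble(measure = gxescore:::measure_names(n_measures),
                                     beta_G = 0, beta_E = 0, beta_GxE = 0))
}
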