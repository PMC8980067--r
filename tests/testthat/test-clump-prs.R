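make_gwas_for <- function(geno, weight, p_value, effect = NULL, other = NULL) {
  v <- geno$variants
  tibble::tibble(
    id = v$id, chrom = v$chrom, pos = v$pos,
    effect_allele = effect %||% v$alt, other_allele = other %||% v$ref,
    weight = weight, p_value = p_value
  )
}

test_that("clumping keeps the most significant variant of a correlated pair", {
  withr::with_seed(301, {
    x <- rbinom(300, 2, 0.4)
  })
  d <- cbind(v1 = x, v2 = x, v3 = rbinom(300, 2, 0.4))
  g <- make_geno_fixture(d, pos = c(1000L, 2000L, 500000L))
  gwas <- make_gwas_for(g, weight = c(0.3, 0.2, 0.1),
                        p_value = c(1e-4, 1e-8, 0.5))
  kept <- greedy_clump(gwas, g, r2_threshold = 0.1, window_kb = 250)
  expect_true("v2" %in% kept)   # smaller p wins
  expect_false("v1" %in% kept)
  expect_true("v3" %in% kept)   # outside any window on same chrom? in LD ~ 0
})

test_that("r2 threshold above 1 keeps every variant with distinct dosages", {
  withr::with_seed(302, {
    d <- sapply(1:10, function(i) rbinom(80, 2, 0.4))
  })
  colnames(d) <- sprintf("v%02d", 1:10)
  g <- make_geno_fixture(d, pos = 1000L * (1:10))
  gwas <- make_gwas_for(g, weight = runif(10), p_value = runif(10))
  kept <- greedy_clump(gwas, g, r2_threshold = 1.0001, window_kb = 250)
  expect_setequal(kept, g$variants$id)
})

test_that("clumping matches the brute-force oracle on a 30-variant fixture", {
  cfg <- sim_config(n_subjects = 150, n_bds = 75, n_snps = 30,
                    ld_block_size = 5, ld_rho = 0.85, n_probes = 10,
                    n_signal_probes = 0, seed = 303)
  g <- simulate_genotypes(cfg)
  withr::with_seed(304, {
    gwas <- make_gwas_for(g, weight = rnorm(30, 0, 0.2), p_value = runif(30))
  })
  for (thr in c(0.05, 0.2, 0.5)) {
    expect_equal(greedy_clump(gwas, g, thr, 250),
                 clump_oracle(gwas, g, thr, 250),
                 label = sprintf("r2 threshold %.2f", thr))
  }
})

test_that("allele alignment flips, drops ambiguous and reports mismatches", {
  d <- matrix(c(0, 1, 2, 2, 1, 0, 1, 1, 1, 0, 2, 1), 4, 3)
  colnames(d) <- c("v1", "v2", "v3")
  g <- make_geno_fixture(d, ref = c("A", "A", "A"), alt = c("C", "C", "C"))
  gwas <- tibble::tibble(
    id = c("v1", "v2", "v3"), chrom = 1L, pos = c(1000L, 2000L, 3000L),
    effect_allele = c("C", "A", "G"), other_allele = c("A", "C", "T"),
    weight = c(0.5, 0.5, 0.5), p_value = 0.01
  )
  suppressMessages(al <- align_alleles(gwas, g$variants))
  expect_equal(al$status, c("ok", "ok", "mismatch"))
  expect_equal(al$flip, c(FALSE, TRUE, FALSE))

  # A/T pair is strand-ambiguous
  g2 <- make_geno_fixture(d[, 1, drop = FALSE], ref = "A", alt = "T")
  gwas2 <- tibble::tibble(id = "v1", chrom = 1L, pos = 1000L,
                          effect_allele = "T", other_allele = "A",
                          weight = 1, p_value = 0.01)
  suppressMessages(al2 <- align_alleles(gwas2, g2$variants))
  expect_equal(al2$status, "ambiguous")
  al3 <- align_alleles(gwas2, g2$variants, drop_ambiguous = FALSE)
  expect_equal(al3$status, "ok")
})

test_that("PRS arithmetic matches hand calculation, with REF-effect flip", {
  d <- matrix(c(2, 0, 1, 1), 2, 2)
  colnames(d) <- c("v1", "v2")
  g <- make_geno_fixture(d, pos = c(1000L, 500000L),
                         ref = c("A", "A"), alt = c("C", "C"))
  gwas <- tibble::tibble(
    id = c("v1", "v2"), chrom = 1L, pos = c(1000L, 500000L),
    effect_allele = c("C", "A"), other_allele = c("A", "C"),
    weight = c(0.1, -0.2), p_value = c(0.01, 0.01)
  )
  prs <- compute_prs(g, gwas, c("v1", "v2"), p_threshold = 0.05)
  # subject 1: 0.1*2 + (-0.2)*(2-1) = 0.0 ; subject 2: 0.1*0 + (-0.2)*(2-1)
  expect_equal(prs$scores$score, c(0.0, -0.2), tolerance = 1e-12)

  # all-zero weights give all-zero scores
  gwas0 <- gwas; gwas0$weight <- 0
  expect_equal(compute_prs(g, gwas0, c("v1", "v2"), 0.05)$scores$score, c(0, 0))

  # empty variant set at the threshold: zero scores with a warning
  expect_warning(p0 <- compute_prs(g, gwas, c("v1", "v2"), 1e-6), "no variants")
  expect_equal(p0$scores$score, c(0, 0))
})

test_that("missing dosages are imputed at twice the effect-allele frequency", {
  d <- matrix(c(2, 0, NA, 1, 1, 1), 3, 2)
  colnames(d) <- c("v1", "v2")
  g <- make_geno_fixture(d, pos = c(1000L, 500000L))
  gwas <- make_gwas_for(g, weight = c(1, 0), p_value = c(0.01, 0.01))
  prs <- compute_prs(g, gwas, c("v1", "v2"), 0.05)
  # observed EAF of v1 = (2+0)/4 = 0.5; imputed aligned dosage = 1
  expect_equal(prs$scores$score[3], 1)
})

test_that("centered PRS is invariant under allele-label + weight-sign flips", {
  cfg <- sim_config(n_subjects = 100, n_bds = 50, n_snps = 60,
                    missing_rate = 0.03, n_probes = 10, n_signal_probes = 0,
                    seed = 305)
  co <- simulate_cohort(cfg)
  g <- co$genotypes
  gwas <- co$gwas
  clumped <- greedy_clump(gwas, g)
  flipped <- gwas
  flipped$effect_allele <- gwas$other_allele
  flipped$other_allele <- gwas$effect_allele
  flipped$weight <- -gwas$weight
  for (pt in c(0.05, 0.2, 0.5)) {
    a <- suppressWarnings(suppressMessages(compute_prs(g, gwas, clumped, pt)))
    b <- suppressWarnings(suppressMessages(compute_prs(g, flipped, clumped, pt)))
    expect_equal(a$scores$score - mean(a$scores$score),
                 b$scores$score - mean(b$scores$score), tolerance = 1e-12,
                 label = sprintf("p_T %.2f", pt))
  }
})

test_that("variant sets are nested across the threshold grid", {
  cfg <- sim_config(n_subjects = 80, n_bds = 40, n_snps = 120, n_probes = 10,
                    n_signal_probes = 0, seed = 306)
  co <- simulate_cohort(cfg)
  clumped <- greedy_clump(co$gwas, co$genotypes)
  grid <- seq(0.05, 0.5, by = 0.05)
  sets <- lapply(grid, function(pt) {
    suppressMessages(compute_prs(co$genotypes, co$gwas, clumped, pt))$variant_ids
  })
  for (i in seq_along(grid)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
    # the increment involves only variants in the p-value band
    extra <- setdiff(sets[[i]], sets[[i - 1]])
    pv <- co$gwas$p_value[match(extra, co$gwas$id)]
    expect_true(all(pv > grid[i - 1] & pv <= grid[i]))
  }
})

test_that("threshold optimization selects the planted optimum region", {
  run_one <- function(s) {
    cfg <- sim_config(n_subjects = 300, n_bds = 150, n_snps = 400, ld_rho = 0,
                      n_probes = 10, n_signal_probes = 0, seed = s)
    g <- simulate_genotypes(cfg)
    withr::with_seed(s + 5000, {
      m <- 400
      causal <- sample(m, 20)
      w <- rnorm(m, 0, 0.25)
      w[causal] <- sample(c(-1, 1), 20, TRUE) * runif(20, 0.2, 0.4)
      p <- runif(m)
      p[causal] <- runif(20, 0.001, 0.04)  # all planted SNPs below p_T = 0.05
      gwas <- make_gwas_for(g, weight = w, p_value = p)
      true_score <- as.numeric(scale(g$dosage[, causal] %*% w[causal]))
      fh <- rbinom(300, 1, plogis(-0.5 + 2 * true_score))
    })
    clumped <- greedy_clump(gwas, g)
    prs <- suppressWarnings(suppressMessages(
      optimize_threshold(g, gwas, clumped, fh)))
    prs$p_threshold
  }
  selected <- vapply(301:312, run_one, numeric(1))
  expect_gte(mean(selected <= 0.05), 0.8)
})

test_that("threshold scan handles a single-point grid and separation", {
  cfg <- sim_config(n_subjects = 60, n_bds = 30, n_snps = 40, n_probes = 10,
                    n_signal_probes = 0, seed = 307)
  co <- simulate_cohort(cfg)
  clumped <- greedy_clump(co$gwas, co$genotypes)
  fh <- co$subjects$family_history
  one <- suppressWarnings(suppressMessages(
    optimize_threshold(co$genotypes, co$gwas, clumped, fh, grid = 0.07)))
  expect_equal(one$p_threshold, 0.07)
  expect_equal(nrow(one$scan), 1)

  # family history perfectly separable by the score: those thresholds are
  # flagged non-converged and excluded from selection (or, if no threshold
  # converges, the scan errors explicitly)
  prs0 <- suppressMessages(compute_prs(co$genotypes, co$gwas, clumped, 0.5))
  fh_sep <- as.numeric(prs0$scores$score > median(prs0$scores$score))
  sep_res <- tryCatch(
    suppressWarnings(suppressMessages(
      optimize_threshold(co$genotypes, co$gwas, clumped, fh_sep,
                         grid = c(0.4, 0.5)))),
    error = function(e) e
  )
  if (inherits(sep_res, "error")) {
    expect_match(conditionMessage(sep_res), "converged")
  } else {
    expect_true(all(sep_res$scan$converged[
      sep_res$scan$p_threshold == sep_res$p_threshold]))
  }

  expect_error(optimize_threshold(co$genotypes, co$gwas, clumped,
                                  rep(1, 60)), "non-empty")
})
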