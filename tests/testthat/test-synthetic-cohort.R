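test_that("config invariants are enforced", {
  expect_error(sim_config(n_causal_snps = 50, n_snps = 20))
  expect_error(sim_config(n_signal_probes = 50, n_probes = 20))
  expect_error(sim_config(n_bds = 100, n_subjects = 50))
  expect_error(sim_config(ld_rho = 1))
  expect_error(sim_config(maf_range = c(0, 0.5)))
})

test_that("generators are fully deterministic under a fixed seed", {
  cfg <- sim_config(n_subjects = 30, n_bds = 15, n_snps = 60, n_probes = 80,
                    n_signal_probes = 5, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$methylation$beta, b$methylation$beta)
  expect_identical(a$gwas, b$gwas)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$brain, b$brain)
})

test_that("genotypes are valid dosages in HWE with MAF-controlled frequencies", {
  cfg <- sim_config(n_subjects = 2000, n_bds = 1000, n_snps = 60,
                    ld_rho = 0.3, maf_range = c(0.5, 0.5), n_probes = 10,
                    n_signal_probes = 0, n_causal_snps = 5, seed = 21)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosage %in% 0:2))
  # at MAF 0.5 and large n, genotype frequencies approach (0.25, 0.5, 0.25)
  freq <- rbind(colMeans(g$dosage == 0), colMeans(g$dosage == 1),
                colMeans(g$dosage == 2))
  expect_lt(max(abs(freq - c(0.25, 0.5, 0.25))), 0.06)

  # >= 99% of variants pass the HWE >= 1e-6 filter when simulated in HWE
  cfg2 <- sim_config(n_subjects = 300, n_bds = 150, n_snps = 500,
                     n_probes = 10, n_signal_probes = 0, seed = 22)
  g2 <- simulate_genotypes(cfg2)
  pvals <- gxescore:::hwe_exact_p(colSums(g2$dosage == 0),
                                  colSums(g2$dosage == 1),
                                  colSums(g2$dosage == 2))
  expect_gte(mean(pvals >= 1e-6), 0.99)
})

test_that("within-block LD is monotone in ld_rho and absent at rho = 0", {
  mean_block_r2 <- function(rho, seed) {
    cfg <- sim_config(n_subjects = 400, n_bds = 200, n_snps = 100,
                      ld_block_size = 10, ld_rho = rho, n_probes = 10,
                      n_signal_probes = 0, seed = seed)
    g <- simulate_genotypes(cfg)
    r2 <- c()
    for (b in seq_len(10)) {
      idx <- ((b - 1) * 10 + 1):(b * 10)
      cm <- cor(g$dosage[, idx])^2
      r2 <- c(r2, cm[upper.tri(cm)])
    }
    mean(r2)
  }
  r2s <- vapply(c(0, 0.4, 0.8), mean_block_r2, numeric(1), seed = 31)
  expect_true(all(diff(r2s) > 0))
  # rho = 0: mean r^2 of independent variables is ~ 1/(n-1)
  expect_lt(abs(r2s[1] - 1 / 399), 3 / 399)
})

test_that("GWAS weights plant causal signal and a clean null", {
  cfg <- sim_config(n_subjects = 50, n_bds = 25, n_snps = 400,
                    n_causal_snps = 0, n_probes = 10, n_signal_probes = 0,
                    seed = 41)
  g <- simulate_genotypes(cfg)
  tr <- make_cohort_truth(cfg, g)
  # with no causal SNPs, p-values are Uniform(0,1): KS across several seeds
  ks_ok <- vapply(1:20, function(s) {
    cfg_s <- sim_config(n_subjects = 50, n_bds = 25, n_snps = 400,
                        n_causal_snps = 0, n_probes = 10,
                        n_signal_probes = 0, seed = 41 + s)
    gw <- simulate_gwas_weights(cfg_s, tr, g)
    suppressWarnings(ks.test(gw$p_value, "punif")$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(ks_ok), 0.9)

  cfg2 <- sim_config(n_subjects = 50, n_bds = 25, n_snps = 400,
                     n_causal_snps = 25, n_probes = 10, n_signal_probes = 0,
                     seed = 43)
  g2 <- simulate_genotypes(cfg2)
  tr2 <- make_cohort_truth(cfg2, g2)
  gw2 <- simulate_gwas_weights(cfg2, tr2, g2)
  expect_true(all(tr2$causal_snp_ids %in% gw2$id))
  expect_true(all(is.finite(gw2$weight)))
  expect_true(all(gw2$p_value > 0 & gw2$p_value <= 1))
  expect_true(all(gw2$p_value[gw2$id %in% tr2$causal_snp_ids] < 1e-3))
  # effect/other alleles are consistent with the genotype records
  al <- merge(gw2, g2$variants, by = "id")
  expect_true(all((al$effect_allele == al$alt & al$other_allele == al$ref) |
                    (al$effect_allele == al$ref & al$other_allele == al$alt)))
})

test_that("methylation betas are in (0,1) and planted shifts are recoverable", {
  cfg <- sim_config(n_subjects = 200, n_bds = 100, n_snps = 20,
                    n_probes = 300, n_signal_probes = 8,
                    probe_effect_delta = 0.2, seed = 51)
  g <- simulate_genotypes(cfg)
  tr <- make_cohort_truth(cfg, g)
  grp <- rep(c("BDS", "non-BDS"), each = 100)
  me <- simulate_methylation(cfg, tr, grp)
  expect_true(all(me$beta > 0 & me$beta < 1))

  # two-sample mean difference at signal probes recovers the planted shift
  # (type I probes only: type II compression shrinks beta-scale differences)
  bds <- grp == "BDS"
  t1 <- me$probes$design_type[match(tr$signal_probe_ids, me$probes$probe_id)] == "I"
  for (j in which(t1)) {
    pid <- tr$signal_probe_ids[j]
    dirn <- tr$true_probe_directions[j]
    d_obs <- mean(me$beta[bds, pid]) - mean(me$beta[!bds, pid])
    se <- sqrt(var(me$beta[bds, pid]) / sum(bds) +
                 var(me$beta[!bds, pid]) / sum(!bds))
    expect_lt(abs(d_obs - 0.2 * dirn), 3 * se + 0.02)
  }

  # delta = 0 leaves signal probes at null
  cfg0 <- sim_config(n_subjects = 200, n_bds = 100, n_snps = 20,
                     n_probes = 300, n_signal_probes = 8,
                     probe_effect_delta = 0, seed = 52)
  me0 <- simulate_methylation(cfg0, tr, grp)
  diffs <- colMeans(me0$beta[bds, tr$signal_probe_ids]) -
    colMeans(me0$beta[!bds, tr$signal_probe_ids])
  expect_lt(max(abs(diffs)), 0.05)
})

test_that("brain measures follow the generative linear model", {
  # null config: no effects, no covariates, no shared component
  cfg <- sim_config(n_subjects = 500, n_bds = 250, n_snps = 10, n_probes = 10,
                    n_signal_probes = 0, n_causal_snps = 0, n_measures = 6,
                    n_affected_measures = 0, noise_sd = 1,
                    measure_shared_sd = 0,
                    covariate_effects = c(age = 0, age2 = 0, gender = 0,
                                          race = 0, smoking = 0), seed = 61)
  tr <- null_truth(6)
  covs <- make_covariates(500, seed = 62)
  withr::with_seed(63, {
    brain <- simulate_brain_measures(cfg, tr, rnorm(500), rnorm(500), covs)
  })
  vars <- vapply(setdiff(names(brain), "subject_id"),
                 function(m) var(brain[[m]]), numeric(1))
  expect_lt(max(abs(vars - 1)), 0.2)

  # planted interaction recovered by OLS on the true design
  cfg2 <- sim_config(n_subjects = 300, n_bds = 150, n_snps = 10, n_probes = 10,
                     n_signal_probes = 0, n_causal_snps = 0, n_measures = 1,
                     n_affected_measures = 1, beta_G = 0, beta_E = 0,
                     beta_GxE = 0.5, noise_sd = 1, seed = 64)
  tr2 <- list(true_effects = tibble::tibble(measure = "m", beta_G = 0,
                                            beta_E = 0, beta_GxE = 0.5))
  covs2 <- make_covariates(300, seed = 65)
  withr::with_seed(66, {
    G <- rnorm(300); E <- rnorm(300)
  })
  brain2 <- simulate_brain_measures(cfg2, tr2, G, E, covs2)
  fit <- summary(lm(brain2$m ~ scale(G) * scale(E) + age + I(age^2) + gender +
                      race + smoking, data = covs2))$coefficients
  ix <- grep(":", rownames(fit))
  expect_lt(abs(fit[ix, 1] - 0.5), 3 * fit[ix, 2])
})

test_that("simulated clinical proxies track the molecular truth", {
  cfg <- sim_config(n_subjects = 400, n_bds = 200, n_snps = 200,
                    n_probes = 200, n_signal_probes = 10, seed = 71)
  co <- simulate_cohort(cfg)
  expect_true(all(co$subjects$cles >= 0 & co$subjects$cles <= 11))
  expect_gt(cor(co$subjects$cles, co$scores_true$mps_true), 0.1)
  fh_fit <- glm(co$subjects$family_history ~ co$scores_true$prs_true,
                family = binomial())
  expect_gt(coef(fh_fit)[2], 0)
  expect_equal(sum(co$subjects$group == "BDS"), 200)
})

test_that("mendelian_child transmits one allele per parent", {
  withr::with_seed(81, {
    pa <- sample(0:2, 500, replace = TRUE)
    pb <- sample(0:2, 500, replace = TRUE)
  })
  ch <- mendelian_child(pa, pb, seed = 82)
  expect_true(all(ch %in% 0:2))
  # homozygote parents force transmission
  expect_true(all(ch[pa == 2 & pb == 2] == 2))
  expect_true(all(ch[pa == 0 & pb == 0] == 0))
  expect_true(all(ch[pa == 2 & pb == 0] == 1))
})
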