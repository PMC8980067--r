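make_model_data <- function(n = 120, seed = 901, beta = 0, beta_gxe = 0) {
  covs <- make_covariates(n, seed = seed)
  withr::with_seed(seed + 1, {
    g <- rnorm(n); e <- rnorm(n)
    y <- beta * g + beta_gxe * g * e + 0.02 * covs$age +
      0.3 * (covs$gender == "Male") + rnorm(n)
  })
  cbind(data.frame(y = y, g = g, e = e), covs)
}

test_that("cohort description reproduces count/percent and test choices", {
  subjects <- tibble::tibble(
    subject_id = sprintf("s%03d", 1:119),
    group = rep(c("BDS", "non-BDS"), c(55, 64)),
    family_history = c(rep(1, 25), rep(0, 30), rep(1, 3), rep(0, 61)),
    cles = c(rep(5, 51), rep(0, 4), rep(4, 45), rep(0, 19))
  )
  subjects$childhood_trauma <- as.integer(subjects$cles > 0)
  tab <- describe_cohort(subjects, variables = c("family_history",
                                                 "childhood_trauma", "cles"))
  pick <- function(v, lv, gr) {
    tab$pct[tab$variable == v & tab$level == lv & tab$group == gr]
  }
  expect_equal(pick("family_history", "1", "BDS"), 100 * 25 / 55,
               tolerance = 1e-12)
  expect_equal(pick("family_history", "1", "non-BDS"), 100 * 3 / 64,
               tolerance = 1e-12)
  expect_equal(round(pick("family_history", "1", "BDS"), 1), 45.5)
  expect_equal(round(pick("family_history", "1", "non-BDS"), 1), 4.7)
  expect_equal(round(pick("childhood_trauma", "1", "non-BDS"), 1), 70.3)
  ct_p <- unique(tab$p[tab$variable == "childhood_trauma"])
  expect_lt(ct_p, 0.01)

  # identical balanced groups: zero chi-squared statistic, p = 1
  even <- tibble::tibble(group = rep(c("A", "B"), each = 40),
                         flag = rep(c(0, 1, 0, 1), each = 20))
  tab2 <- describe_cohort(even, variables = "flag")
  expect_equal(unique(tab2$p), 1)
  expect_equal(unique(tab2$test), "chisq")

  # sparse cells fall back to Fisher's exact test
  sparse <- tibble::tibble(group = rep(c("A", "B"), each = 10),
                           flag = c(rep(0, 9), 1, rep(0, 8), 1, 1))
  tab3 <- describe_cohort(sparse, variables = "flag")
  expect_equal(unique(tab3$test), "fisher")

  # continuous variables: median/IQR and the rank-sum test
  tab4 <- describe_cohort(subjects, variables = "cles")
  expect_equal(tab4$median[tab4$group == "BDS"], 5)
  expect_equal(unique(tab4$test), "wilcoxon")
})

test_that("standardize_measures yields exact z-scores and flags degeneracy", {
  withr::with_seed(902, {
    brain <- tibble::tibble(subject_id = sprintf("s%02d", 1:30),
                            m1 = rnorm(30, 100, 5), m2 = runif(30))
  })
  std <- standardize_measures(brain)
  expect_lt(max(abs(colMeans(std[, c("m1", "m2")]))), 1e-10)
  expect_equal(apply(std[, c("m1", "m2")], 2, sd), c(m1 = 1, m2 = 1),
               tolerance = 1e-10)
  # affine invariance
  brain2 <- brain
  brain2$m1 <- 3 * brain$m1 - 7
  expect_equal(standardize_measures(brain2)$m1, std$m1, tolerance = 1e-10)
  brain$m2 <- 1
  expect_error(standardize_measures(brain), "m2")
})

test_that("spearman_corr equals rank-then-Pearson and handles edge cases", {
  expect_equal(spearman_corr(1:10, (1:10)^3), 1)
  expect_equal(spearman_corr(1:10, -(1:10)), -1)
  expect_true(is.na(spearman_corr(rep(1, 10), 1:10)))
  withr::with_seed(903, {
    for (i in 1:10) {
      x <- sample(1:5, 30, replace = TRUE)   # heavy ties
      y <- rnorm(30)
      expect_equal(spearman_corr(x, y),
                   cor(rank(x), rank(y)),
                   tolerance = 1e-12)
      expect_equal(spearman_corr(x, y), cor(x, y, method = "spearman"),
                   tolerance = 1e-12)
    }
  })
})

test_that("partial_r2 follows the SSR-ratio definition", {
  expect_equal(partial_r2(10, 10), 0)
  expect_equal(partial_r2(0, 10), 1)
  expect_equal(partial_r2(6.63, 10), 0.337)
  expect_error(partial_r2(1, 0), "zero residual")
  expect_warning(r <- partial_r2(11, 10), "clipped")
  expect_equal(r, 0)
})

test_that("partial R2 equals the algebraic R2 identity on random fixtures", {
  withr::with_seed(904, {
    for (i in 1:25) {
      n <- sample(30:80, 1)
      X <- matrix(rnorm(n * 3), n, 3)
      z <- rnorm(n)
      y <- X %*% rnorm(3) + 0.5 * z + rnorm(n)
      full <- lm(y ~ X + z)
      cov_only <- lm(y ~ X)
      lhs <- partial_r2(sum(resid(full)^2), sum(resid(cov_only)^2))
      r2f <- summary(full)$r.squared
      r2c <- summary(cov_only)$r.squared
      expect_equal(lhs, (r2f - r2c) / (1 - r2c), tolerance = 1e-10)
    }
  })
})

test_that("main-effect fit recovers planted coefficients and matches the F-test", {
  d <- make_model_data(n = 300, seed = 905, beta = 0.5)
  res <- fit_main_model(d, "y", "g")
  expect_lt(abs(res$beta - 0.5), 3 * res$se)
  expect_equal(res$n_used, 300)

  # p equals the brute-force nested-model F-test for a single added regressor
  covs <- c("age", "I(age^2)", "gender", "race", "smoking")
  full <- lm(reformulate(c("g", covs), "y"), d)
  cov_only <- lm(reformulate(covs, "y"), d)
  f <- anova(cov_only, full)
  expect_equal(res$p, f$`Pr(>F)`[2], tolerance = 1e-12)
  expect_equal(res$partial_r2,
               1 - sum(resid(full)^2) / sum(resid(cov_only)^2),
               tolerance = 1e-12)

  # a factor that duplicates a covariate up to noise explains ~nothing
  d$fake <- d$age + rnorm(300, sd = 1e-4)
  res2 <- fit_main_model(d, "y", "fake")
  expect_lt(res2$partial_r2, 0.01)
  # exact collinearity is a rank-deficiency error naming the column
  d$dup <- d$g
  expect_error(
    fit_main_model(d, "y", "dup", covariates = c("age", "gender", "race",
                                                 "smoking", "g")),
    "rank deficient")
})

test_that("main-effect inference is invariant to affine covariate rescaling", {
  d <- make_model_data(n = 150, seed = 906, beta = 0.3)
  a <- fit_main_model(d, "y", "g")
  d2 <- d
  d2$age <- (d$age - 20) / 10
  covs2 <- c("age", "gender", "race", "smoking")
  b <- fit_main_model(d2, "y", "g", covariates = covs2)
  expect_equal(a$beta, b$beta, tolerance = 1e-8)
  expect_equal(a$p, b$p, tolerance = 1e-8)
  expect_equal(a$partial_r2, b$partial_r2, tolerance = 1e-8)
})

test_that("interaction fit recovers a planted product effect with power", {
  hits <- vapply(1:10, function(s) {
    d <- make_model_data(n = 300, seed = 910 + s, beta_gxe = 0.5)
    res <- fit_interaction_model(d, "y", "g", "e")
    c(within3 = abs(res$beta - 0.5) <= 3 * res$se, sig = res$p < 0.05)
  }, logical(2))
  expect_gte(mean(hits["within3", ]), 0.9)
  expect_gt(mean(hits["sig", ]), 0.8)

  # centered product with zero mains: main effects stay near zero
  d <- make_model_data(n = 400, seed = 921, beta_gxe = 0.6)
  covs <- c("age", "I(age^2)", "gender", "race", "smoking")
  fit <- summary(lm(reformulate(c("g", "e", "g:e", covs), "y"), d))$coefficients
  expect_lt(abs(fit["g", 1]), 3 * fit["g", 2])
  expect_lt(abs(fit["e", 1]), 3 * fit["e", 2])
})

test_that("storey q-values reduce to BH at pi0 = 1 and behave monotonically", {
  withr::with_seed(930, {
    for (i in 1:50) {
      p <- runif(sample(15:150, 1))
      q <- storey_qvalues(p, pi0 = 1)
      expect_equal(q, bh_oracle(p), tolerance = 0)
      o <- order(p)
      expect_true(all(diff(q[o]) >= 0))
    }
  })
  expect_equal(storey_qvalues(rep(1, 20)), rep(1, 20))
  withr::with_seed(932, p5 <- runif(5))
  expect_warning(qq <- storey_qvalues(p5), "fewer than 10")
  expect_equal(qq, bh_oracle(p5), tolerance = 0)
  expect_error(storey_qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("the pi0 estimate is near 1 under the null and small under signal", {
  withr::with_seed(931, {
    p_null <- runif(500)
    p_sig <- c(rbeta(300, 0.2, 5), runif(200))
  })
  # under the null, q ~ BH-scale (pi0 close to 1)
  q_null <- storey_qvalues(p_null)
  expect_gt(min(q_null / bh_oracle(p_null)), 0.7)
  # with substantial signal, pi0 < 1 makes q smaller than BH
  q_sig <- storey_qvalues(p_sig)
  expect_lt(median(q_sig / bh_oracle(p_sig)), 0.9)
})

test_that("bootstrap comparison is centered for self-comparison and deterministic", {
  n <- 100
  covs <- make_covariates(n, seed = 940)
  withr::with_seed(941, {
    d <- cbind(data.frame(y = rnorm(n), g1 = rnorm(n), e1 = rnorm(n)), covs)
  })
  d$g2 <- d$g1
  d$e2 <- d$e1
  res <- bootstrap_compare_partial_r2(d, "y", c("g1", "e1"), c("g2", "e2"),
                                      n_boot = 400, seed = 942)
  expect_equal(res$delta_partial_r2, 0, tolerance = 1e-12)
  expect_gte(res$p_boot, 0.3)
  expect_lte(res$p_boot, 0.7)

  res2 <- bootstrap_compare_partial_r2(d, "y", c("g1", "e1"), c("g2", "e2"),
                                       n_boot = 400, seed = 942)
  expect_identical(res$p_boot, res2$p_boot)
  expect_identical(res$delta_boot_q025, res2$delta_boot_q025)
})

test_that("a planted molecular advantage is detected by the bootstrap", {
  hits <- vapply(1:10, function(s) {
    n <- 200
    covs <- make_covariates(n, seed = 950 + s)
    withr::with_seed(960 + s, {
      g2 <- rnorm(n); e2 <- rnorm(n)
      y <- 0.45 * g2 + 0.45 * e2 + rnorm(n)  # molecular pair explains ~0.3
      d <- cbind(data.frame(y = y, g1 = rnorm(n), e1 = rnorm(n),
                            g2 = g2, e2 = e2), covs)
    })
    bootstrap_compare_partial_r2(d, "y", c("g1", "e1"), c("g2", "e2"),
                                 n_boot = 300, seed = s)$p_boot < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("bootstrap p is conservative, never anti-conservative, under the null", {
  pb <- vapply(1:60, function(s) {
    n <- 100
    covs <- make_covariates(n, seed = 970 + s)
    withr::with_seed(1040 + s, {
      d <- cbind(data.frame(y = rnorm(n), g1 = rnorm(n), e1 = rnorm(n),
                            g2 = rnorm(n), e2 = rnorm(n)), covs)
    })
    bootstrap_compare_partial_r2(d, "y", c("g1", "e1"), c("g2", "e2"),
                                 n_boot = 200, seed = s)$p_boot
  }, numeric(1))
  expect_lte(mean(pb <= 0.05), 0.08)   # one-sided tail not inflated
  expect_lte(mean(pb >= 0.95), 0.10)
  expect_gt(median(pb), 0.25)
  expect_lt(median(pb), 0.75)
})
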