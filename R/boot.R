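#' Bootstrap comparison of clinical vs molecular partial R-squared
#'
#' Resamples subjects with replacement `n_boot` times; each run refits the two
#' interaction models (clinical pair, e.g. family history and CLES; molecular
#' pair, e.g. PRS and MPS) and records
#' `delta = partialR2_molecular - partialR2_clinical`. The one-sided bootstrap
#' p-value (default; direction: molecular higher) is the proportion of
#' resampled deltas below 0, counting exact ties at 0 with half weight; a
#' two-sided option doubles the smaller tail.
#' Rank-deficient resamples are redrawn and counted. Deterministic given
#' `seed`.
#'
#' @param data Data frame with the measure, both factor pairs and covariates.
#' @param measure Brain-measure column.
#' @param clinical_pair,molecular_pair Length-2 character vectors
#'   `(g_factor, e_factor)`.
#' @param covariates Covariate columns (`"age"` implies the squared term).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @param alternative `"greater"` (molecular higher; default) or `"two.sided"`.
#' @return One-row tibble: `measure`, `partial_r2_clinical`,
#'   `partial_r2_molecular`, `delta_partial_r2`, `delta_boot_q025`,
#'   `delta_boot_q975`, `p_boot`, `n_boot`, `n_redrawn`.
#' @export
bootstrap_compare_partial_r2 <- function(data, measure,
                                         clinical_pair, molecular_pair,
                                         covariates = c("age", "gender",
                                                        "race", "smoking"),
                                         n_boot = 2000, seed = 1L,
                                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(clinical_pair) == 2, length(molecular_pair) == 2)
  used <- unique(c(measure, clinical_pair, molecular_pair, covariates))
  validate_table(data, used, "model data")
  d <- data[complete.cases(data[, used]), , drop = FALSE]
  for (v in c(clinical_pair, molecular_pair)) {
    d[[v]] <- as_binary_numeric(d[[v]], v)
  }
  covs <- covariate_terms(covariates)
  y <- d[[measure]]
  n <- length(y)

  design <- function(pair) {
    f <- reformulate(c(pair[1], pair[2], paste0(pair[1], ":", pair[2]), covs))
    model.matrix(f, data = d)
  }
  Xc <- design(clinical_pair)
  Xm <- design(molecular_pair)
  Xcov <- model.matrix(reformulate(covs), data = d)

  pr2_pair <- function(idx, X) {
    fit_full <- lm.fit(X[idx, , drop = FALSE], y[idx])
    if (fit_full$rank < ncol(X)) return(NA_real_)
    fit_cov <- lm.fit(Xcov[idx, , drop = FALSE], y[idx])
    if (fit_cov$rank < ncol(Xcov)) return(NA_real_)
    ssr_cov <- sum(fit_cov$residuals^2)
    if (ssr_cov == 0) return(NA_real_)
    min(max(1 - sum(fit_full$residuals^2) / ssr_cov, 0), 1)
  }

  obs_c <- pr2_pair(seq_len(n), Xc)
  obs_m <- pr2_pair(seq_len(n), Xm)
  if (is.na(obs_c) || is.na(obs_m)) {
    stop("observed-data fits are rank deficient or saturated", call. = FALSE)
  }

  n_redrawn <- 0L
  delta <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        dc <- pr2_pair(idx, Xc)
        dm <- pr2_pair(idx, Xm)
        if (!is.na(dc) && !is.na(dm)) return(dm - dc)
        n_redrawn <<- n_redrawn + 1L
        if (n_redrawn > 100L * n_boot) {
          stop("too many degenerate bootstrap resamples", call. = FALSE)
        }
      }
    }, numeric(1))
  })
  # mid-p handling of exact ties at 0 (degenerate only for identical pairs)
  p_low <- mean(delta < 0) + 0.5 * mean(delta == 0)
  p_high <- mean(delta > 0) + 0.5 * mean(delta == 0)
  p_boot <- switch(alternative,
                   greater = p_low,
                   two.sided = min(1, 2 * min(p_low, p_high)))
  tibble(measure = measure,
         partial_r2_clinical = obs_c, partial_r2_molecular = obs_m,
         delta_partial_r2 = obs_m - obs_c,
         delta_boot_q025 = unname(quantile(delta, 0.025)),
         delta_boot_q975 = unname(quantile(delta, 0.975)),
         p_boot = p_boot, n_boot = n_boot, n_redrawn = n_redrawn)
}
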