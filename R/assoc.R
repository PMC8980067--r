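# Covariate-adjusted association models on standardized brain measures.

#' Standardize brain measures
#'
#' Z-scores every measure column over the analysis subjects (mean 0, SD 1,
#' n - 1 denominator). Errors naming any zero-variance measure.
#'
#' @param brain Brain-measure tibble with a `subject_id` column.
#' @param measures Columns to standardize (default: all but `subject_id`).
#' @return The tibble with standardized measure columns.
#' @export
standardize_measures <- function(brain, measures = NULL) {
  if (is.null(measures)) measures <- setdiff(names(brain), "subject_id")
  if (nrow(brain) < 2) stop("need at least 2 subjects", call. = FALSE)
  for (mcol in measures) brain[[mcol]] <- zscore(brain[[mcol]], mcol)
  brain
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged) over pairwise-complete
#' observations; `NA` when either vector is constant or fewer than 3 pairs
#' remain.
#'
#' @param x,y Numeric vectors.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
spearman_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  xr <- rank(x[ok], ties.method = "average")
  yr <- rank(y[ok], ties.method = "average")
  if (sd(xr) == 0 || sd(yr) == 0) return(NA_real_)
  cor(xr, yr)
}

#' Partial R-squared from residual sums of squares
#'
#' `1 - SSR_full / SSR_cov` for a covariate-only model nested in the full
#' model on the same subjects; clipped to \[0, 1\] with a warning when the
#' raw value falls outside (possible only for non-nested fits).
#'
#' @param ssr_full,ssr_cov Residual sums of squares.
#' @return Partial R-squared in \[0, 1\].
#' @export
partial_r2 <- function(ssr_full, ssr_cov) {
  if (ssr_cov < 0 || ssr_full < 0) stop("SSR must be non-negative", call. = FALSE)
  if (ssr_cov == 0) {
    stop("covariate-only model has zero residual sum of squares", call. = FALSE)
  }
  r <- 1 - ssr_full / ssr_cov
  if (r < 0 || r > 1) {
    warning(sprintf("partial R-squared %.4g clipped to [0, 1]", r), call. = FALSE)
    r <- min(max(r, 0), 1)
  }
  r
}

# Expand the covariate list to model terms; "age" implies the age^2 term.
covariate_terms <- function(covariates) {
  unlist(lapply(covariates, function(v) {
    if (v == "age") c("age", "I(age^2)") else v
  }))
}

# Guard against rank deficiency: error naming aliased columns.
check_full_rank <- function(fit) {
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop(sprintf("model is rank deficient; collinear term(s): %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")), call. = FALSE)
  }
  invisible(fit)
}

#' Covariate-adjusted main-effect model for one brain measure
#'
#' Ordinary least squares `measure ~ factor + age + age^2 + gender + race +
#' smoking` on complete cases, returning the factor coefficient with its
#' standard error and two-sided p-value, and the partial R-squared against the
#' covariate-only model fitted on the same subjects. Two-level non-numeric
#' factors are coerced to 0/1.
#'
#' @param data Data frame containing the measure, factor and covariates.
#' @param measure,factor Column names.
#' @param covariates Covariate columns (default
#'   `c("age", "gender", "race", "smoking")`; `"age"` implies the squared
#'   term).
#' @return One-row tibble: `measure`, `factor`, `beta`, `se`, `p`,
#'   `partial_r2`, `n_used`.
#' @export
fit_main_model <- function(data, measure, factor,
                           covariates = c("age", "gender", "race", "smoking")) {
  covs <- covariate_terms(covariates)
  used <- unique(c(measure, factor, covariates))
  validate_table(data, used, "model data")
  d <- data[complete.cases(data[, used]), , drop = FALSE]
  d[[factor]] <- as_binary_numeric(d[[factor]], factor)

  full <- lm(reformulate(c(factor, covs), response = measure), data = d)
  check_full_rank(full)
  covfit <- lm(reformulate(covs, response = measure), data = d)
  cf <- summary(full)$coefficients
  pr2 <- partial_r2(sum(resid(full)^2), sum(resid(covfit)^2))
  tibble(measure = measure, factor = factor,
         beta = cf[factor, 1], se = cf[factor, 2], p = cf[factor, 4],
         partial_r2 = pr2, n_used = nrow(d))
}

#' Gene-environment interaction model for one brain measure
#'
#' OLS `measure ~ G + E + G:E + covariates` on complete cases; reports the
#' interaction coefficient and the partial R-squared of the three-term factor
#' block (G, E, G:E) against the covariate-only model on the same subjects.
#'
#' @inheritParams fit_main_model
#' @param g_factor,e_factor Genetic and environmental factor columns (e.g.
#'   PRS and MPS, or family history and CLES).
#' @return One-row tibble: `measure`, `g_factor`, `e_factor`, `beta`, `se`,
#'   `p` (all for the interaction term), `partial_r2` (block), `n_used`.
#' @export
fit_interaction_model <- function(data, measure, g_factor, e_factor,
                                  covariates = c("age", "gender", "race",
                                                 "smoking")) {
  covs <- covariate_terms(covariates)
  used <- unique(c(measure, g_factor, e_factor, covariates))
  validate_table(data, used, "model data")
  d <- data[complete.cases(data[, used]), , drop = FALSE]
  d[[g_factor]] <- as_binary_numeric(d[[g_factor]], g_factor)
  d[[e_factor]] <- as_binary_numeric(d[[e_factor]], e_factor)

  inter <- paste0(g_factor, ":", e_factor)
  full <- lm(reformulate(c(g_factor, e_factor, inter, covs), response = measure),
             data = d)
  check_full_rank(full)
  covfit <- lm(reformulate(covs, response = measure), data = d)
  cf <- summary(full)$coefficients
  pr2 <- partial_r2(sum(resid(full)^2), sum(resid(covfit)^2))
  tibble(measure = measure, g_factor = g_factor, e_factor = e_factor,
         beta = cf[inter, 1], se = cf[inter, 2], p = cf[inter, 4],
         partial_r2 = pr2, n_used = nrow(d))
}
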