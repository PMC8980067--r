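#' Logit (M-value) transform of methylation betas
#'
#' `M = log_base(beta / (1 - beta))`, base 2 by default (the field's M-value
#' convention). The transform is invertible via [m_to_beta()].
#'
#' @param meth A [meth_matrix()] or a beta matrix in (0, 1).
#' @param base Logarithm base (default 2).
#' @return M-value matrix (subjects x probes).
#' @export
logit_transform <- function(meth, base = 2) {
  beta <- if (inherits(meth, "meth_matrix")) meth$beta else as.matrix(meth)
  if (any(beta <= 0 | beta >= 1)) {
    stop("beta values must lie strictly inside (0, 1)", call. = FALSE)
  }
  log(beta / (1 - beta), base = base)
}

#' @rdname logit_transform
#' @param m M-value matrix.
#' @export
m_to_beta <- function(m, base = 2) {
  e <- base^m
  e / (1 + e)
}

# Stratified fold assignment: shuffles within each class, then deals folds
# cyclically, so every fold sees both classes.
stratified_folds <- function(y, k, seed = 1L) {
  with_seed(seed, {
    f <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
}

#' Fit the LASSO methylation profile score model
#'
#' L1-penalized logistic regression of BDS status on M-values over a lambda
#' path (probes standardized internally by glmnet; weights reported on the
#' M-value scale). Lambda is chosen by stratified k-fold cross-validated
#' binomial deviance with the one-standard-error rule by default. The selected
#' probes are the nonzero coefficients; the intercept is excluded from the
#' score.
#'
#' @param m_matrix M-value matrix (subjects x probes).
#' @param group_labels BDS indicator: 0/1, logical, or two-level labels where
#'   `"BDS"` (when present) is the positive class.
#' @param nfolds Cross-validation folds (default 5).
#' @param rule `"1se"` (default) or `"min"`.
#' @param lambda Optional fixed lambda; skips cross-validation.
#' @param seed Seed for the fold assignment.
#' @return An `mps_model`: `probes` (tibble `probe_id`, `weight`),
#'   `intercept`, `lambda`, `rule`, `cv` (lambda path table), `n_selected`.
#' @export
fit_lasso_mps <- function(m_matrix, group_labels, nfolds = 5,
                          rule = c("1se", "min"), lambda = NULL, seed = 1L) {
  rule <- match.arg(rule)
  y <- if (is.numeric(group_labels) || is.logical(group_labels)) {
    as.numeric(group_labels)
  } else {
    lev <- sort(unique(group_labels))
    pos <- if ("BDS" %in% lev) "BDS" else lev[length(lev)]
    as.numeric(group_labels == pos)
  }
  if (length(unique(y)) < 2) stop("both classes must be non-empty", call. = FALSE)
  x <- as.matrix(m_matrix)

  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "binomial", lambda = lambda)
    cf <- as.matrix(coef(fit, s = lambda))
    cv_tab <- NULL
    lambda_used <- lambda
  } else {
    foldid <- stratified_folds(y, nfolds, seed = seed)
    cvfit <- glmnet::cv.glmnet(x, y, family = "binomial",
                               type.measure = "deviance", foldid = foldid)
    lambda_used <- if (rule == "1se") cvfit$lambda.1se else cvfit$lambda.min
    cf <- as.matrix(coef(cvfit, s = lambda_used))
    cv_tab <- tibble(lambda = cvfit$lambda, cvm = cvfit$cvm,
                     cvsd = cvfit$cvsd, nzero = as.integer(cvfit$nzero))
  }
  w <- cf[-1, 1]
  sel <- which(w != 0)
  if (length(sel) == 0) {
    warning("all coefficients are zero at the chosen lambda; MPS will be 0",
            call. = FALSE)
  }
  structure(
    list(probes = tibble(probe_id = colnames(x)[sel], weight = unname(w[sel])),
         intercept = cf[1, 1], lambda = lambda_used, rule = rule,
         cv = cv_tab, n_selected = length(sel)),
    class = "mps_model"
  )
}

#' @export
print.mps_model <- function(x, ...) {
  cat(sprintf("<mps_model> %d probes selected at lambda = %.4g (%s rule)\n",
              x$n_selected, x$lambda, x$rule))
  invisible(x)
}

#' @export
tidy.mps_model <- function(x, ...) x$probes

#' @export
glance.mps_model <- function(x, ...) {
  tibble(n_selected = x$n_selected, lambda = x$lambda, rule = x$rule,
         intercept = x$intercept)
}

#' Compute the methylation profile score
#'
#' `MPS = sum_i w_i x_i` over the model's selected probes, where `x_i` is the
#' subject's M-value; the intercept is excluded. Errors listing any model
#' probes absent from the matrix.
#'
#' @param m_matrix M-value matrix (subjects x probes).
#' @param model An [fit_lasso_mps()] model.
#' @return Tibble `subject_id`, `score`.
#' @export
compute_mps <- function(m_matrix, model) {
  x <- as.matrix(m_matrix)
  sid <- rownames(x) %||% sprintf("S%04d", seq_len(nrow(x)))
  if (model$n_selected == 0) {
    return(tibble(subject_id = sid, score = rep(0, nrow(x))))
  }
  absent <- setdiff(model$probes$probe_id, colnames(x))
  if (length(absent) > 0) {
    stop(sprintf("model probes absent from the matrix: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  score <- as.numeric(x[, model$probes$probe_id, drop = FALSE] %*%
                        model$probes$weight)
  tibble(subject_id = sid, score = score)
}
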