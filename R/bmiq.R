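# Beta-mixture quantile (BMIQ) normalization of Illumina type II probes.
#
# Per subject, a 3-state (unmethylated / hemimethylated / methylated) beta
# mixture is fitted by EM separately to type I and type II probe betas; type
# II probes in the outer states are quantile-mapped onto the matching type I
# state distribution, and hemimethylated probes are carried across by a
# dilation (linear) transform between the mapped outer states. Type I probes
# are left untouched.

# Deterministic 3-component beta-mixture EM. Components are initialized from
# fixed beta cutpoints (falling back to terciles when a group is tiny) and
# updated by weighted method-of-moments, which is stable for the tight,
# well-separated states of methylation data.
fit_beta_mixture3 <- function(x, tol = 1e-5, maxit = 200) {
  x <- clamp_unit(x)
  g <- cut(x, c(-Inf, 0.25, 0.75, Inf), labels = FALSE)
  if (min(tabulate(g, 3)) < 5) {
    g <- cut(x, quantile(x, c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
             labels = FALSE)
  }
  mom <- function(w) {
    mu <- weighted.mean(x, w)
    v <- max(weighted.mean((x - mu)^2, w), 1e-6)
    v <- min(v, 0.95 * mu * (1 - mu))
    phi <- mu * (1 - mu) / v - 1
    c(a = max(mu * phi, 0.05), b = max((1 - mu) * phi, 0.05))
  }
  resp <- vapply(1:3, function(k) as.numeric(g == k), numeric(length(x)))
  pi_k <- colMeans(resp)
  ab <- vapply(1:3, function(k) mom(resp[, k]), numeric(2))
  loglik <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    dens <- vapply(1:3, function(k) pi_k[k] * dbeta(x, ab[1, k], ab[2, k]),
                   numeric(length(x)))
    rs <- rowSums(dens)
    rs[rs == 0 | !is.finite(rs)] <- .Machine$double.xmin
    new_loglik <- sum(log(rs))
    resp <- dens / rs
    pi_k <- pmax(colMeans(resp), 1e-8)
    pi_k <- pi_k / sum(pi_k)
    ab <- vapply(1:3, function(k) mom(resp[, k]), numeric(2))
    if (is.finite(loglik) &&
        abs(new_loglik - loglik) < tol * (abs(loglik) + 1)) {
      loglik <- new_loglik
      converged <- TRUE
      break
    }
    loglik <- new_loglik
  }
  means <- ab[1, ] / (ab[1, ] + ab[2, ])
  ord <- order(means)  # U < H < M
  list(a = ab[1, ord], b = ab[2, ord], pi = pi_k[ord],
       resp = resp[, ord, drop = FALSE],
       state = c("U", "H", "M")[apply(resp[, ord, drop = FALSE], 1, which.max)],
       converged = converged, niter = it, loglik = loglik)
}

# Map one subject's type II betas onto the type I state distributions.
bmiq_map_subject <- function(b2, fit1, fit2, eps = 1e-6) {
  state <- fit2$state
  new <- b2
  for (s in c("U", "M")) {
    k <- match(s, c("U", "H", "M"))
    idx <- state == s
    if (!any(idx)) return(NULL)
    p <- pbeta(b2[idx], fit2$a[k], fit2$b[k])
    new[idx] <- qbeta(pmin(pmax(p, eps), 1 - eps), fit1$a[k], fit1$b[k])
  }
  hemi <- state == "H"
  if (any(hemi)) {
    maxU2 <- max(b2[state == "U"]); minM2 <- min(b2[state == "M"])
    minH2 <- min(b2[hemi]); maxH2 <- max(b2[hemi])
    tU <- max(new[state == "U"]); tM <- min(new[state == "M"])
    if (tM <= tU) return(NULL)
    gapL <- max(minH2 - maxU2, 0)
    gapR <- max(minM2 - maxH2, 0)
    span <- maxH2 - minH2
    f <- if (span > 0) (tM - tU - gapL - gapR) / span else 0
    if (!is.finite(f) || f <= 0) {
      # overlapping states: plain linear interpolation across the gap
      gapL <- 0; gapR <- 0
      f <- if (span > 0) (tM - tU) / span else 0
    }
    new[hemi] <- tU + gapL + (b2[hemi] - minH2) * f
  }
  clamp_unit(new, eps)
}

#' BMIQ normalization of type II probes
#'
#' @param meth A [meth_matrix()] with `design_type` available for all probes.
#' @param em_tol EM relative log-likelihood tolerance (default 1e-5).
#' @param em_maxit Maximum EM iterations (default 200).
#' @param min_state_size Minimum probes assigned per state; subjects whose
#'   fits fall below it (or whose EM fails to converge) keep their unadjusted
#'   betas, with a warning.
#' @return A [meth_matrix()] with normalized type II betas; type I betas are
#'   bit-identical to the input. An attribute `bmiq_failed` lists subjects
#'   that fell back to unadjusted values.
#' @export
bmiq_normalize <- function(meth, em_tol = 1e-5, em_maxit = 200,
                           min_state_size = 5) {
  t1 <- which(meth$probes$design_type == "I")
  t2 <- which(meth$probes$design_type == "II")
  if (length(t1) < 3 * min_state_size || length(t2) < 3 * min_state_size) {
    warning("too few probes of one design type; returning input unchanged",
            call. = FALSE)
    return(meth)
  }
  beta <- meth$beta
  failed <- character(0)
  for (i in seq_len(nrow(beta))) {
    f1 <- tryCatch(fit_beta_mixture3(beta[i, t1], tol = em_tol, maxit = em_maxit),
                   error = function(e) NULL)
    f2 <- tryCatch(fit_beta_mixture3(beta[i, t2], tol = em_tol, maxit = em_maxit),
                   error = function(e) NULL)
    ok <- !is.null(f1) && !is.null(f2) && f1$converged && f2$converged &&
      min(tabulate(match(f1$state, c("U", "H", "M")), 3)) >= min_state_size &&
      min(tabulate(match(f2$state, c("U", "H", "M")), 3)) >= min_state_size
    mapped <- if (ok) bmiq_map_subject(beta[i, t2], f1, f2) else NULL
    if (is.null(mapped)) {
      failed <- c(failed, rownames(beta)[i])
    } else {
      beta[i, t2] <- mapped
    }
  }
  if (length(failed) > 0) {
    warning(sprintf("BMIQ fell back to unadjusted betas for %d subject(s)",
                    length(failed)), call. = FALSE)
  }
  out <- meth_matrix(beta, meth$probes, detection_p = meth$detection_p,
                     bead_count = meth$bead_count)
  attr(out, "bmiq_failed") <- failed
  out
}
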