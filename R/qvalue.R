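#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`, extrapolates to
#' `lambda -> 1` with a cubic smoothing spline, clips the estimate to (0, 1],
#' and converts p-values to q-values by the step-up rule
#' `q_i = min over j with p_j >= p_i of pi0 m p_j / rank(p_j)`. With fewer
#' than 10 p-values pi0 is fixed at 1 (the Benjamini-Hochberg special case)
#' with a warning.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param lambda Grid for pi0 estimation (default `seq(0.05, 0.95, 0.05)`).
#' @param pi0 Optional fixed pi0 overriding estimation (e.g. 1 for BH).
#' @return Vector of q-values, monotone non-decreasing in p.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05), pi0 = NULL) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  }
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 10) {
      warning("fewer than 10 p-values: pi0 fixed at 1 (Benjamini-Hochberg)",
              call. = FALSE)
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      sp <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- predict(sp, x = max(lambda))$y
      pi0 <- min(max(pi0, 1 / m), 1)  # clip to (0, 1]
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q_sorted <- cummin(pi0 * m * p[o] / (m:1))
  pmin(q_sorted, 1)[ro]
}
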