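#' Paired partial R-squared bar plot (interaction models)
#'
#' For each brain measure, side-by-side bars of the partial R-squared of the
#' clinical (family history x CLES) and molecular (PRS x MPS) interaction
#' models.
#'
#' @param x A `gxe_analysis` object or its `interactions` tibble.
#' @return A ggplot object.
#' @export
plot_partial_r2 <- function(x) {
  d <- if (inherits(x, "gxe_analysis")) x$interactions else as_tibble(x)
  validate_table(d, c("measure", "pair", "partial_r2"), "interactions")
  ord <- d |>
    dplyr::filter(.data$pair == "molecular") |>
    dplyr::arrange(dplyr::desc(.data$partial_r2)) |>
    dplyr::pull(.data$measure)
  d$measure <- factor(d$measure, levels = ord)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$measure, y = .data$partial_r2,
                                  fill = .data$pair)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::scale_fill_manual(values = c(clinical = "grey55",
                                          molecular = "#2166AC"),
                               name = "factor pair") +
    ggplot2::labs(x = NULL, y = expression("partial " * R^2),
                  title = "Gene-environment interaction models") +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' PRS threshold-scan plot
#'
#' -log10 of the logistic (family history ~ PRS) coefficient p-value across
#' the p-value-threshold grid, with the selected threshold marked.
#'
#' @param prs A `prs_result` from [optimize_threshold()].
#' @return A ggplot object.
#' @export
plot_threshold_scan <- function(prs) {
  if (is.null(prs$scan)) stop("no scan table; run optimize_threshold()",
                              call. = FALSE)
  d <- prs$scan[prs$scan$converged, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p_threshold, y = -log10(.data$p))) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = prs$p_threshold, linetype = 2,
                        color = "#B2182B") +
    ggplot2::labs(x = expression(p[T]), y = expression(-log[10](p)),
                  title = sprintf("PRS threshold scan (selected p_T = %g)",
                                  prs$p_threshold)) +
    ggplot2::theme_minimal(base_size = 10)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.gxe_analysis <- function(object, ...) plot_partial_r2(object)

#' @export
autoplot.prs_result <- function(object, ...) plot_threshold_scan(object)
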