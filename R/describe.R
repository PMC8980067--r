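#' Cohort description by group
#'
#' Per variable, by group: count and percent of non-missing for categorical
#' variables (numeric variables with at most two distinct values are treated
#' as categorical), median and interquartile range for continuous ones.
#' Dichotomous/categorical variables are compared with the chi-squared test
#' without continuity correction, falling back to Fisher's exact test when any
#' expected cell count is below 5; continuous variables use the Wilcoxon
#' rank-sum test (normal approximation with tie correction).
#'
#' @param subjects Subject tibble.
#' @param group Name of the grouping column (default `"group"`).
#' @param variables Variables to summarize; defaults to every column except
#'   `subject_id` and the group.
#' @return Long tibble: `variable`, `type`, `level`, `group`, `n`, `denom`,
#'   `pct`, `median`, `q1`, `q3`, `p`, `test`.
#' @export
describe_cohort <- function(subjects, group = "group", variables = NULL) {
  validate_table(subjects, group, "subjects")
  if (is.null(variables)) {
    variables <- setdiff(names(subjects), c("subject_id", group))
  }
  g <- subjects[[group]]
  glev <- sort(unique(g[!is.na(g)]))

  purrr::map_dfr(variables, function(v) {
    x <- subjects[[v]]
    continuous <- is.numeric(x) && length(unique(x[!is.na(x)])) > 2
    if (continuous) {
      pval <- tryCatch(
        wilcox.test(x ~ factor(g), exact = FALSE, correct = FALSE)$p.value,
        error = function(e) NA_real_
      )
      purrr::map_dfr(glev, function(gl) {
        xs <- x[g == gl & !is.na(x)]
        tibble(variable = v, type = "continuous", level = NA_character_,
               group = as.character(gl), n = length(xs), denom = length(xs),
               pct = NA_real_, median = median(xs),
               q1 = unname(quantile(xs, 0.25)), q3 = unname(quantile(xs, 0.75)),
               p = pval, test = "wilcoxon")
      })
    } else {
      ok <- !is.na(x) & !is.na(g)
      tab <- table(x[ok], g[ok])
      test <- "chisq"
      pval <- NA_real_
      if (nrow(tab) >= 2 && ncol(tab) >= 2) {
        expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (any(expected < 5)) {
          test <- "fisher"
          pval <- fisher.test(tab)$p.value
        } else {
          pval <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
        }
      }
      levels_x <- sort(unique(as.character(x[ok])))
      purrr::map_dfr(levels_x, function(lv) {
        purrr::map_dfr(glev, function(gl) {
          denom <- sum(ok & g == gl)
          nn <- sum(ok & g == gl & as.character(x) == lv)
          tibble(variable = v, type = "categorical", level = lv,
                 group = as.character(gl), n = nn, denom = denom,
                 pct = 100 * nn / denom, median = NA_real_,
                 q1 = NA_real_, q3 = NA_real_, p = pval, test = test)
        })
      })
    }
  })
}
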