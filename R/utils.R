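# Internal helpers shared across modules.

# Evaluate `code` with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs user RNG flow.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Clamp values into the open unit interval; methylation betas use eps = 1e-6.
clamp_unit <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

#' Validate that a table carries the required columns
#'
#' Schema gate applied before any computation starts: errors with the table
#' name and the full list of missing columns.
#'
#' @param df A data frame.
#' @param required Character vector of required column names.
#' @param name Label used in the error message.
#' @return `df`, invisibly, when valid.
#' @export
validate_table <- function(df, required, name = deparse(substitute(df))) {
  if (!is.data.frame(df)) {
    stop(sprintf("'%s' must be a data frame", name), call. = FALSE)
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf(
      "table '%s' is missing required column(s): %s",
      name, paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

# Coerce a two-level factor/character/logical to a 0/1 numeric vector.
# Numeric input is passed through unchanged.
as_binary_numeric <- function(x, name = "variable") {
  if (is.numeric(x)) return(x)
  if (is.logical(x)) return(as.numeric(x))
  lev <- sort(unique(x[!is.na(x)]))
  if (length(lev) > 2) {
    stop(sprintf("'%s' has %d levels; expected at most 2 or a numeric vector",
                 name, length(lev)), call. = FALSE)
  }
  as.numeric(match(x, lev) - 1L)
}

# z-score with the n-1 denominator; errors on zero variance.
zscore <- function(x, name = "variable") {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stop(sprintf("measure '%s' has zero variance and cannot be standardized",
                 name), call. = FALSE)
  }
  (x - mean(x, na.rm = TRUE)) / s
}
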