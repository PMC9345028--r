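#' @useDynLib dysglyc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois rlnorm rbinom quantile median sd setNames predict
#' @importFrom utils head tail write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Report-display rounding (half-up), as opposed to the IEC round-half-even
#' rule used by [round()]. Raw values are always retained internally; this is
#' only applied when percentages are formatted for reports.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percentage of a count ratio
#'
#' Convenience used throughout reporting: `100 * num / den`, rounded half-up.
#'
#' @param num numerator count
#' @param den denominator count
#' @param digits decimals to keep (default 2, as in the package's reports)
#' @return percentage
#' @export
report_pct <- function(num, den, digits = 2) {
  round_half_up(100 * num / den, digits)
}

# hours between two POSIXct vectors (b - a)
hours_between <- function(a, b) as.numeric(difftime(b, a, units = "hours"))

# deterministic child seed streams derived from one integer seed
# (double arithmetic: products exceed .Machine$integer.max)
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(k) * 9176) %% 2147483629)
}

# evaluate expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_if_not_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("table '%s' is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
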