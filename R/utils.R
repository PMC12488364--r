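#' Round half away from zero
#'
#' Reported percentages use commercial rounding (0.5 always rounds away
#' from zero), not banker's rounding, so that e.g. 62.5% prints as 63%.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places (default 0).
#' @return rounded numeric vector; `NA` stays `NA`.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' z-based confidence interval of a mean from summary statistics
#'
#' Normal-quantile interval `mean +/- z * sd / sqrt(n)` at the given
#' coverage. This is the mechanism behind both the control-cohort
#' biomarker cut-offs and the descriptive group summaries.
#'
#' @param mean,sd,n summary statistics (sample SD, n-1 denominator).
#' @param level coverage in (0,1); default 0.95.
#' @return named numeric vector `c(low, high)`.
#' @export
ci_of_mean <- function(mean, sd, n, level = 0.95) {
  stopifnot(level > 0, level < 1, n >= 1, sd >= 0)
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sd / sqrt(n)
  c(low = mean - half, high = mean + half)
}

# Canonical item order: plain lexicographic on the label bytes, fixed
# locale-independent via the C collation wrapper below. Every itemset in
# the package is stored in this order so set identity == vector identity.
sort_items <- function(items) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  sort(unique(items))
}

# Separator used in machine-readable rule strings ("A & B"); display
# output may swap in the set-intersection glyph.
ITEM_SEP <- " & "

join_items <- function(items) paste(sort_items(items), collapse = ITEM_SEP)

split_items <- function(s) strsplit(s, ITEM_SEP, fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
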