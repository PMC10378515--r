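#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Commercial/clinical reports round 0.5 up, unlike [base::round()]'s
#' round-half-even. Used by every percentage formatter in the package.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a percentage under the cohort-report convention
#'
#' Values of 10% or more print as integers, values below 10% with one
#' decimal, both rounded half up. This reproduces published cohort-table
#' renderings such as 66, 51, 3.5 or 16.
#'
#' @param count integer numerator.
#' @param denom integer denominator.
#' @return character percentage (no "%" sign); `NA` when `denom` is 0.
#' @export
format_pct <- function(count, denom) {
  out <- rep(NA_character_, length(count))
  ok <- !is.na(denom) & denom > 0
  p <- 100 * count[ok] / denom[ok]
  out[ok] <- ifelse(p >= 10,
    formatC(round_half_up(p, 0), format = "d"),
    formatC(round_half_up(p, 1), format = "f", digits = 1)
  )
  out
}

# Curated symbol alias map: published texts occasionally print variant
# spellings (digit-for-letter typos, legacy names); keys are already
# normalized forms of the aliases.
.SYMBOL_ALIASES <- c(
  T1CAM1 = "TICAM1",
  IF1H1  = "IFIH1",
  IFR3   = "IRF3",
  ACE1   = "ACE",
  MACS   = "MCAS"
)

#' Normalize a gene symbol
#'
#' Uppercases, strips characters outside `[A-Z0-9-]`, and applies a curated
#' alias map for known published misspellings (e.g. "T1CAM1" for TICAM1).
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalize_symbol <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- gsub("[^A-Z0-9-]", "", x)
  hit <- x %in% names(.SYMBOL_ALIASES)
  x[hit] <- unname(.SYMBOL_ALIASES[x[hit]])
  x
}

#' Sample from a truncated normal distribution
#'
#' Inverse-CDF sampling; exact (no rejection loop), so draws consume one
#' uniform each and the generator stays reproducible for a fixed seed.
#'
#' @param n number of draws.
#' @param mean,sd moments of the parent normal.
#' @param lower,upper truncation bounds.
#' @return numeric vector of length `n`.
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}
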