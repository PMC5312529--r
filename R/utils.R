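# Shared numeric helpers.  Time units: survival in months (365.25/12 days),
# PK in hours.  Units are never implicit: column names carry them.

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the convention
#' of clinical tables, unlike [round()]'s round-half-even).  A one-ulp guard
#' protects values such as 21.55 that binary floating point stores just below
#' the tie.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector of the same length.
#' @examples
#' round_half_up(c(0.25, -0.25, 21.55), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Geometric mean and log-scale percent CV
#'
#' `geomean()` is `exp(mean(log(x)))`; `geocv_pct()` is the lognormal
#' coefficient of variation `100 * sqrt(exp(s^2) - 1)` with `s` the standard
#' deviation of `log(x)` -- the convention used for pharmacokinetic cohort
#' summaries.
#'
#' @param x positive numeric vector.
#' @return a scalar.
#' @export
geomean <- function(x) exp(mean(log(x)))

#' @rdname geomean
#' @export
geocv_pct <- function(x) {
  if (length(x) < 2) return(0)
  100 * sqrt(exp(stats::var(log(x))) - 1)
}

# percentage string with one decimal, round-half-up (table rendering)
fmt_pct1 <- function(x) sprintf("%.1f", round_half_up(100 * x, 1))

# internal: derive independent replicate seeds from one master seed
replicate_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
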