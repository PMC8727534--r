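#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when formatting percentages and
#' signal statistics for report tables. Base \code{round()} rounds half to
#' even, which disagrees with printed pharmacovigilance tables at .xx5.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(17.575, 2)  # 17.58, not 17.57
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a denominator, half-up at 2 decimals
#'
#' @param k numerator count(s).
#' @param n denominator.
#' @param digits decimal places (default 2, matching report tables).
#' @return percentage(s) on the 0--100 scale; 0 when \code{n} is 0.
#' @export
pct_half_up <- function(k, n, digits = 2) {
  if (length(n) == 1 && n == 0) return(rep(0, length(k)))
  round_half_up(100 * k / n, digits)
}

# Quartiles by linear interpolation between order statistics (quantile type 7).
# One fixed convention for every median/IQR in the package.
quartiles <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
}

# message-level logging used by the readers/builders; kept quiet inside tests
pv_log <- function(...) {
  if (isTRUE(getOption("faerspv.quiet", FALSE))) return(invisible(NULL))
  message(...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
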