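#' Round half away from zero
#'
#' Presentation rounding used throughout the package when comparing computed
#' values against published tables: exact halves round up (`0.845` -> `0.85`),
#' unlike [base::round()]'s round-half-even. Internal computations are never
#' rounded; this is applied only when a value is displayed or matched against
#' a printed figure.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(16.3775, 1) # 16.4
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# shared binomial SE of a proportion
binom_se <- function(p, n) sqrt(p * (1 - p) / n)

`%||%` <- function(a, b) if (is.null(a)) b else a
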