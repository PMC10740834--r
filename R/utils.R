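#' Round half away from zero
#'
#' Commercial rounding: ties go away from zero, unlike [base::round()] which
#' rounds half to even. Used wherever a printed count or table cell is
#' reproduced (e.g. top-k variant counts).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(0.5)    # 1, not 0
#' round_half_away(2.5)    # 3
#' round_half_away(8.2845, 3)
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with call. = FALSE everywhere; keeps messages clean for script users
stop2 <- function(...) stop(..., call. = FALSE)

assert_scalar_in <- function(x, lo, hi, name, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop2(sprintf("`%s` must be a single number in %s%g, %g%s",
                  name, if (lo_open) "(" else "[", lo, hi,
                  if (hi_open) ")" else "]"))
  }
  invisible(x)
}
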