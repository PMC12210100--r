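#' Round half away from zero
#'
#' Rounding convention used throughout the reporting layer: ties are rounded
#' away from zero (so 0.33125 at 4 decimals gives 0.3313), matching how
#' association tables in the dairy-genetics literature are printed. Base R's
#' `round()` uses round-half-to-even and would print 0.3312.
#'
#' A tiny tolerance (1e-9) absorbs binary floating-point representation error
#' in the shifted value, so values that are exact ties in decimal are treated
#' as ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
#' @examples
#' round_half_away(0.33125, 4) # 0.3313
#' round_half_away(-0.08925, 4) # -0.0893
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Significance stars
#'
#' @param p numeric vector of p-values.
#' @return character vector: `"**"` for p < 0.01, `"*"` for p < 0.05, else `""`.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

# format numeric for the fixed-precision TSV reporting layer
.fmt4 <- function(x) {
  formatC(round_half_away(x, 4), format = "f", digits = 4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
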