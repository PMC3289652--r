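#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even (banker's rounding); published
#' diagnostic tables conventionally round half away from zero (0.5 -> 1,
#' 82.5 -> 83). Used wherever proportions are displayed as integer percent.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.8209 * 100) # 82
#' round_half_up(82.5)         # 83, where round() gives 82
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Percentage string formatting used by the table writers.
fmt_pct <- function(p) {
  ifelse(is.na(p), NA_character_, paste0(round_half_up(100 * p), "%"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
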