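#' Clip values to the unit interval
#'
#' @param x numeric vector.
#' @return `x` with values below 0 set to 0 and above 1 set to 1.
#' @keywords internal
clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Render log10 molar doses the way dosing tables print them
#'
#' Doses on the 1/3-log grid are conventionally written with two decimals
#' (-8.67, -8.33) while whole-log doses drop the decimals (-9, -8).
#'
#' @param x numeric vector of log10 molar doses.
#' @return character vector, one rendered dose per element.
#' @examples
#' render_log_dose(c(-11, -32/3, -31/3, -10))
#' @export
render_log_dose <- function(x) {
  vapply(x, function(v) {
    r <- round(v, 2)
    if (abs(r - round(r)) < 1e-9) {
      as.character(as.integer(round(r)))
    } else {
      sprintf("%.2f", r)
    }
  }, character(1))
}

# key used to match doses between single-agent and combination arms
dose_key <- function(x) ifelse(is.na(x), "none", sprintf("%.6f", x))
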