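#' Exact unit conversions used throughout the carbon account
#'
#' Converts between the units that appear in the pipeline: square kilometres
#' and hectares (factor 100), tonnes and kilotonnes (factor 1000), and tonnes
#' of carbon and tonnes of CO2 (factor 44/12, the ratio of molecular to atomic
#' weight). Factors are exact rationals, never decimal approximations, so
#' round trips are identities up to floating point.
#'
#' @param value numeric vector to convert.
#' @param from,to unit labels; one of `"km2"`, `"ha"`, `"t"`, `"kt"`,
#'   `"t_C"`, `"t_CO2"`.
#' @return numeric vector in the target units.
#' @examples
#' convert_units(766, "km2", "ha")      # 76600
#' convert_units(1121.7, "t_C", "t_CO2")
#' @export
convert_units <- function(value, from, to) {
  stopifnot(is.numeric(value), length(from) == 1L, length(to) == 1L)
  if (from == to) return(value)
  key <- paste(from, to, sep = "->")
  factor <- switch(key,
    "km2->ha"    = 100,
    "ha->km2"    = 1 / 100,
    "t->kt"      = 1 / 1000,
    "kt->t"      = 1000,
    "t_C->t_CO2" = 44 / 12,
    "t_CO2->t_C" = 12 / 44,
    stop("unsupported unit conversion: ", from, " -> ", to, call. = FALSE)
  )
  value * factor
}

#' Carbon to CO2 mass ratio (44/12), kept exact
#' @keywords internal
CO2_RATIO <- 44 / 12
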