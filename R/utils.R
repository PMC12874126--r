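# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to a fixed number of decimals with ties going away from zero
#' (0.5 -> 1), the convention used when comparing computed values against
#' published tables. Base R's `round()` rounds half to even, which disagrees
#' at exactly-representable ties such as 0.925.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.925, 2)  # 0.93, where round() gives 0.92
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Convert between kcal and kJ
#'
#' Feed energy densities are quoted in kcal/kg in formulation practice and in
#' MJ/kg or kJ in metabolism work; the thermochemical calorie (1 kcal =
#' 4.184 kJ) is used.
#'
#' @param x Numeric vector of energy values.
#' @return Converted numeric vector.
#' @export
kcal_to_kj <- function(x) x * 4.184

#' @rdname kcal_to_kj
#' @export
kj_to_kcal <- function(x) x / 4.184

# Structured error conditions -------------------------------------------

abort_invalid <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("ducknutr_invalid_input", "error", "condition")))
}

abort_config <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("ducknutr_config_error", "error", "condition")))
}

abort_schema <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("ducknutr_schema_error", "error", "condition")))
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    abort_invalid(what, " must be finite and numeric")
  invisible(x)
}
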