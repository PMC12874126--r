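#' Model parameter set for the dynamic requirement equations
#'
#' Bundles every coefficient of the coupled requirement equations
#'
#' \deqn{ME = \alpha W^{0.75} + \beta \cdot BGW + k_3\,\Delta T + BC}
#' \deqn{CP = a W^{0.75} + b \cdot BGW + SF \cdot AAI}
#'
#' together with the correction tables (seasonal factors, temperature-lag
#' damping) and the adaptive growth-stage adjustments. The temperature term is
#' parameterised in deviation form: \eqn{k_3^{cold} \max(0, T_{low} - ET) -
#' k_3^{heat} \max(0, ET - T_{high})} per unit \eqn{W^{0.75}}, so that extra
#' energy is required below the thermoneutral band and the requirement is
#' reduced above it.
#'
#' @param alpha Maintenance-energy coefficient, kJ/(kg^0.75 d). Default 541.7,
#'   the baseline maintenance requirement per unit metabolic body weight.
#' @param beta Growth-energy coefficient, kJ per g of daily gain. Default
#'   19.86 (equivalently 19.86 MJ/kg gain).
#' @param k3_cold Cold-compensation coefficient, kJ/(kg^0.75 °C d), applied to
#'   the shortfall below `t_low`. Must be >= 0. The default 13.0 reproduces a
#'   theoretical compensation of +12 % of baseline maintenance (541.7) for a
#'   cold spell 5 °C below the lower thermoneutral limit
#'   (0.12 x 541.7 / 5); no directly tabulated value exists, so treat it as
#'   a calibration starting point.
#' @param k3_heat Heat-reduction coefficient, kJ/(kg^0.75 °C d), applied to the
#'   excess above `t_high`. Must be >= 0. Default 6.5 (half the cold
#'   response, reflecting the weaker per-degree intake reduction under heat);
#'   also a calibration starting point.
#' @param bc Additive energy offset, kJ/d (default 0; breed-level offsets live
#'   in [breed_profile()] — this slot exists so the offset can be calibrated).
#' @param a Maintenance-protein coefficient, g/(kg^0.75 d). Default 6.013.
#' @param b Growth-protein coefficient, g protein per g gain. Default 0.18
#'   (a configurable engineering default; not a tabulated value).
#' @param sf_table Named numeric vector of seasonal factors for the zones
#'   `cold`, `thermoneutral`, `heat`. Defaults 1.35 / 1.15 / 1.05.
#' @param gamma_table Data frame with columns `n_min` and `gamma` defining the
#'   left-closed steps of the temperature-lag coefficient; days with no cold
#'   spell (n = 0) always map to 1.
#' @param rapid_growth_threshold Daily gain, g/d, above which the adaptive
#'   reallocation of alpha/beta applies. Default 35.
#' @param alpha_adjust Fractional change applied to `alpha` in rapid growth
#'   (default -0.18).
#' @param beta_adjust Fractional change applied to `beta` in rapid growth
#'   (default +0.24).
#' @param summer_bgw_boost Fractional increase of `b` in the heat zone
#'   (default +0.23).
#' @param summer_maint_cut Fractional decrease of `a` in the heat zone
#'   (default -0.18).
#' @param t_low Lower thermoneutral limit, °C (default 15).
#' @param t_high Upper thermoneutral limit, °C (default 28).
#'
#' @return An object of class `model_parameters` (a validated named list).
#' @export
#' @examples
#' p <- model_parameters()
#' p$alpha
#' model_parameters(alpha = 600, k3_cold = 2.5)
model_parameters <- function(alpha = 541.7,
                             beta = 19.86,
                             k3_cold = 13.0,
                             k3_heat = 6.5,
                             bc = 0,
                             a = 6.013,
                             b = 0.18,
                             sf_table = c(cold = 1.35, thermoneutral = 1.15,
                                          heat = 1.05),
                             gamma_table = default_gamma_table(),
                             rapid_growth_threshold = 35,
                             alpha_adjust = -0.18,
                             beta_adjust = 0.24,
                             summer_bgw_boost = 0.23,
                             summer_maint_cut = -0.18,
                             t_low = 15,
                             t_high = 28) {
  p <- structure(
    list(alpha = alpha, beta = beta, k3_cold = k3_cold, k3_heat = k3_heat,
         bc = bc, a = a, b = b, sf_table = sf_table,
         gamma_table = gamma_table,
         rapid_growth_threshold = rapid_growth_threshold,
         alpha_adjust = alpha_adjust, beta_adjust = beta_adjust,
         summer_bgw_boost = summer_bgw_boost,
         summer_maint_cut = summer_maint_cut,
         t_low = t_low, t_high = t_high),
    class = "model_parameters")
  validate_parameters(p)
}

#' Default temperature-lag damping table
#'
#' Step function of the number of consecutive cold days n: damping gamma is
#' 0.85 for 1 <= n < 3, 0.51 for 3 <= n < 5 and 0.32 for n >= 5. n = 0 (no
#' cold spell) is handled outside the table and maps to 1.
#'
#' @return Data frame with columns `n_min` and `gamma`.
#' @export
default_gamma_table <- function() {
  data.frame(n_min = c(1, 3, 5), gamma = c(0.85, 0.51, 0.32))
}

#' Validate a model parameter set
#'
#' @param p A `model_parameters` object (or bare list with the same fields).
#' @return The validated object, invisibly usable in pipelines.
#' @export
validate_parameters <- function(p) {
  if (!is.list(p)) abort_invalid("parameters must be a list")
  for (f in c("alpha", "beta", "b"))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      abort_invalid("parameter '", f, "' must be a single positive number")
  for (f in c("k3_cold", "k3_heat"))
    if (!is.finite(p[[f]]) || p[[f]] < 0)
      abort_invalid("parameter '", f, "' must be >= 0")
  if (!is.finite(p$a) || p$a <= 0)
    abort_invalid("parameter 'a' must be a single positive number")
  if (!is.finite(p$bc)) abort_invalid("parameter 'bc' must be finite")
  zones <- c("cold", "thermoneutral", "heat")
  if (!all(zones %in% names(p$sf_table)))
    abort_config("sf_table must name all three zones: ",
                 paste(setdiff(zones, names(p$sf_table)), collapse = ", "))
  if (any(!is.finite(p$sf_table)) || any(p$sf_table <= 0))
    abort_invalid("seasonal factors must all be positive")
  gt <- p$gamma_table
  if (!is.data.frame(gt) || !all(c("n_min", "gamma") %in% names(gt)) ||
      nrow(gt) < 1)
    abort_config("gamma_table must be a data frame with columns n_min, gamma")
  if (any(gt$gamma <= 0) || any(gt$gamma > 1))
    abort_invalid("gamma_table values must lie in (0, 1]")
  if (is.unsorted(gt$n_min, strictly = TRUE))
    abort_config("gamma_table n_min breakpoints must be strictly increasing")
  if (!is.finite(p$rapid_growth_threshold) || p$rapid_growth_threshold < 0)
    abort_invalid("rapid_growth_threshold must be >= 0")
  if (p$t_low >= p$t_high)
    abort_invalid("t_low must be strictly below t_high")
  p
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Dynamic requirement model parameters\n")
  cat(sprintf("  ME: alpha = %.4g kJ/(kg^0.75 d), beta = %.4g kJ/g,",
              x$alpha, x$beta),
      sprintf("k3_cold = %.4g, k3_heat = %.4g, BC = %.4g kJ/d\n",
              x$k3_cold, x$k3_heat, x$bc))
  cat(sprintf("  CP: a = %.4g g/(kg^0.75 d), b = %.4g g/g\n", x$a, x$b))
  cat(sprintf("  SF: cold %.2f | thermoneutral %.2f | heat %.2f   ",
              x$sf_table[["cold"]], x$sf_table[["thermoneutral"]],
              x$sf_table[["heat"]]),
      sprintf("thermoneutral band [%g, %g] degC\n", x$t_low, x$t_high))
  cat(sprintf("  rapid growth: > %g g/d -> alpha %+.0f%%, beta %+.0f%%\n",
              x$rapid_growth_threshold, 100 * x$alpha_adjust,
              100 * x$beta_adjust))
  invisible(x)
}

# Replace a named subset of scalar coefficients; used by the fitters.
set_parameters <- function(p, values) {
  for (nm in names(values)) p[[nm]] <- unname(values[[nm]])
  validate_parameters(p)
}
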