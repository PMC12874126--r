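# Amino-acid balance index (AAI), its seasonal adjustment, and
# energy-protein ratio interval checks.

#' Diet specification
#'
#' @param me_density Metabolizable energy density of the feed, kcal/kg
#'   (convert with [kcal_to_kj()] / [kj_to_kcal()] when working in MJ/kg).
#' @param cp_pct Crude protein concentration, % of diet.
#' @param lysine_pct Dietary lysine, % of diet.
#' @param methionine_pct Dietary methionine, % of diet.
#' @return An object of class `diet_spec`.
#' @export
#' @examples
#' diet_spec(me_density = 2730, cp_pct = 21, lysine_pct = 0.9,
#'           methionine_pct = 0.3)
diet_spec <- function(me_density, cp_pct, lysine_pct, methionine_pct) {
  for (f in c("me_density", "cp_pct", "lysine_pct", "methionine_pct")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      abort_invalid(f, " must be a single positive number")
  }
  ratio <- lysine_pct / methionine_pct
  if (ratio < 1.5 || ratio > 5.0)
    abort_invalid("lysine:methionine ratio ", signif(ratio, 3),
                  " outside the sanity band [1.5, 5.0]")
  structure(list(me_density = me_density, cp_pct = cp_pct,
                 lysine_pct = lysine_pct, methionine_pct = methionine_pct),
            class = "diet_spec")
}

#' Amino-acid balance index (AAI)
#'
#' Dimensionless index of lysine:methionine balance, computed as the dietary
#' lysine/methionine ratio normalised by a reference ratio. It equals 1 at
#' the reference balance; the default reference 3.0 is the midpoint of the
#' practically relevant 2.8:1–3.2:1 span.
#'
#' @param lysine_pct Dietary lysine, % of diet (> 0, vectorised).
#' @param methionine_pct Dietary methionine, % of diet (> 0, vectorised).
#' @param reference_ratio Reference lysine:methionine ratio (> 0, default 3).
#' @return Dimensionless index.
#' @export
#' @examples
#' compute_aai(0.96, 0.30)  # ratio 3.2 vs reference 3.0 -> 1.0667
compute_aai <- function(lysine_pct, methionine_pct, reference_ratio = 3.0) {
  if (!is.numeric(methionine_pct) || any(methionine_pct <= 0))
    abort_invalid("methionine_pct must be positive")
  if (!is.numeric(lysine_pct) || any(lysine_pct <= 0))
    abort_invalid("lysine_pct must be positive")
  if (!is.numeric(reference_ratio) || any(reference_ratio <= 0))
    abort_invalid("reference_ratio must be positive")
  (lysine_pct / methionine_pct) / reference_ratio
}

#' Seasonal adjustment of the AAI
#'
#' In cold conditions maintenance metabolism raises the relative methionine
#' need, which lowers the balance index (`aai * (1 - kappa)`); under heat
#' stress extra lysine counters muscle breakdown, raising it
#' (`aai * (1 + kappa)`); the thermoneutral zone leaves it unchanged. kappa
#' is the breed's season-amino-acid interaction coefficient.
#'
#' @param aai Balance index (> 0, vectorised).
#' @param zone Season zone from [classify_season()].
#' @param kappa Interaction coefficient; values outside the documented
#'   envelope [0.12, 0.35] trigger a warning, not an error.
#' @return Adjusted AAI.
#' @export
#' @examples
#' seasonal_aai_adjustment(1, "cold", 0.2)  # 0.8
seasonal_aai_adjustment <- function(aai, zone, kappa) {
  if (!is.numeric(aai) || any(aai <= 0)) abort_invalid("aai must be positive")
  if (!is.numeric(kappa) || anyNA(kappa))
    abort_invalid("kappa must be numeric")
  if (any(kappa < 0.12) || any(kappa > 0.35))
    warning("kappa outside the documented envelope [0.12, 0.35]",
            call. = FALSE)
  ifelse(zone == "cold", aai * (1 - kappa),
         ifelse(zone == "heat", aai * (1 + kappa), aai))
}

#' Classify an energy-protein ratio against the optimal interval
#'
#' The optimal feed energy-protein ratio interval is 125–135:1 (kcal/kg feed
#' ME per % CP); ratios inside it are `optimal`, below `below`, above
#' `above`.
#'
#' @param ratio Energy-protein ratio (> 0, vectorised).
#' @return Character vector in `{"below", "optimal", "above"}`.
#' @export
#' @examples
#' check_ep_interval(c(120, 130, 140))
check_ep_interval <- function(ratio) {
  if (!is.numeric(ratio) || any(!is.finite(ratio)) || any(ratio <= 0))
    abort_invalid("ratio must be positive")
  ifelse(ratio < 125, "below", ifelse(ratio > 135, "above", "optimal"))
}

#' High-energy-density warning
#'
#' Protein utilisation declines at feed energy concentrations above
#' 2950 kcal/kg; this flags diets strictly above that threshold.
#'
#' @param me_density Feed ME density, kcal/kg (> 0, vectorised).
#' @return Logical flag vector.
#' @export
#' @examples
#' energy_density_warning(c(2800, 2950, 3000))  # FALSE FALSE TRUE
energy_density_warning <- function(me_density) {
  if (!is.numeric(me_density) || any(me_density <= 0))
    abort_invalid("me_density must be positive")
  me_density > 2950
}
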