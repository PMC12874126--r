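# The coupled requirement equations and the orchestration that assembles a
# full daily requirement from animal state + environment + breed + diet.

#' One animal-day state
#'
#' @param body_weight Live body weight, kg (> 0).
#' @param daily_gain Daily live-weight gain, g/d (>= 0).
#' @param age Age in days (optional, >= 0).
#' @return An object of class `duck_state`.
#' @export
#' @examples
#' duck_state(body_weight = 1.8, daily_gain = 42, age = 21)
duck_state <- function(body_weight, daily_gain, age = NA_real_) {
  check_finite(body_weight, "body_weight")
  check_finite(daily_gain, "daily_gain")
  if (any(body_weight <= 0)) abort_invalid("body_weight must be positive")
  if (any(daily_gain < 0)) abort_invalid("daily_gain must be >= 0")
  if (!all(is.na(age)) && any(age < 0, na.rm = TRUE))
    abort_invalid("age must be >= 0")
  structure(list(body_weight = body_weight, daily_gain = daily_gain,
                 age = age),
            class = "duck_state")
}

#' Growth-stage adaptive coefficients
#'
#' During rapid growth (daily gain above the threshold, default 35 g/d) the
#' marginal contribution of metabolic body weight falls and that of daily
#' gain rises: alpha is reduced by 18 % and beta raised by 24 % by default.
#' Below the threshold the coefficients pass through unchanged, so the
#' adjustment is idempotent for slow-growing states.
#'
#' @param bgw Daily gain, g/d (>= 0, vectorised).
#' @param params A [model_parameters()] object (supplies the threshold and
#'   the fractional adjustments as well as baseline alpha, beta).
#' @return A list with numeric fields `alpha` and `beta` (vectors if `bgw`
#'   is a vector).
#' @export
#' @examples
#' effective_growth_coefficients(40, model_parameters())
effective_growth_coefficients <- function(bgw, params) {
  check_finite(bgw, "bgw")
  if (any(bgw < 0)) abort_invalid("bgw must be >= 0")
  rapid <- bgw > params$rapid_growth_threshold
  list(alpha = ifelse(rapid, params$alpha * (1 + params$alpha_adjust),
                      params$alpha),
       beta = ifelse(rapid, params$beta * (1 + params$beta_adjust),
                     params$beta))
}

#' Metabolizable energy requirement, kJ/d
#'
#' Factorial energy equation: seasonal-factor-scaled maintenance
#' (`sf_m * alpha_eff * W^0.75`), growth (`beta_eff * BGW`), the
#' environmental temperature adjustment and an additive breed offset.
#' `alpha_eff`/`beta_eff` come from [effective_growth_coefficients()], so the
#' rapid-growth reallocation applies automatically.
#'
#' @param state A [duck_state()] (fields may be vectors).
#' @param env_adjustment Temperature adjustment, kJ/d (from
#'   [temperature_adjustment()]; positive in cold, negative in heat).
#' @param sf_m Multiplier on the maintenance term (seasonal factor, possibly
#'   combined with a breed multiplier); must be > 0.
#' @param params A [model_parameters()] object.
#' @param breed_offset Additive breed energy offset, kJ/d.
#' @return Energy requirement, kJ/d, with the per-term breakdown in a
#'   `components` attribute (maintenance, growth, temperature, breed).
#' @export
#' @examples
#' # winter maintenance of a 1-kg duck at zero gain: 541.7 * 1.35 = 731.3
#' compute_me(duck_state(1, 0), env_adjustment = 0, sf_m = 1.35,
#'            params = model_parameters())
compute_me <- function(state, env_adjustment = 0, sf_m = 1,
                       params = model_parameters(), breed_offset = 0) {
  check_finite(state$body_weight, "body_weight")
  check_finite(env_adjustment, "env_adjustment")
  check_finite(breed_offset, "breed_offset")
  if (!is.numeric(sf_m) || any(!is.finite(sf_m)) || any(sf_m <= 0))
    abort_invalid("sf_m must be positive")
  eff <- effective_growth_coefficients(state$daily_gain, params)
  maintenance <- sf_m * eff$alpha * state$body_weight^0.75
  growth <- eff$beta * state$daily_gain
  me <- maintenance + growth + env_adjustment + breed_offset
  attr(me, "components") <- data.frame(maintenance = maintenance,
                                       growth = growth,
                                       temperature = env_adjustment + 0 * me,
                                       breed = breed_offset + 0 * me)
  me
}

#' Crude protein requirement, g/d
#'
#' Factorial protein equation: maintenance (`a_z * W^0.75`), growth
#' (`b_z * BGW`) and the seasonal amino-acid term (`SF * AAI`, g/d). In the
#' heat (summer) zone the maintenance coefficient is cut and the growth
#' coefficient boosted (defaults −18 % and +23 %); other zones use the stored
#' coefficients unchanged.
#'
#' @param state A [duck_state()] (fields may be vectors).
#' @param sf Seasonal factor (> 0), from [seasonal_factor()].
#' @param aai Amino-acid balance index (> 0), from [compute_aai()]; use 1
#'   when no diet is specified.
#' @param params A [model_parameters()] object.
#' @param zone Season zone from [classify_season()].
#' @return Protein requirement, g/d, with the per-term breakdown in a
#'   `components` attribute (maintenance, growth, aa_balance).
#' @export
#' @examples
#' compute_cp(duck_state(1, 20), sf = 1.15, aai = 1.07,
#'            params = model_parameters(), zone = "thermoneutral")
compute_cp <- function(state, sf, aai, params = model_parameters(),
                       zone = "thermoneutral") {
  check_finite(state$body_weight, "body_weight")
  if (!is.numeric(sf) || any(!is.finite(sf)) || any(sf <= 0))
    abort_invalid("sf must be positive")
  if (!is.numeric(aai) || any(!is.finite(aai)) || any(aai <= 0))
    abort_invalid("aai must be positive")
  summer <- zone == "heat"
  a_z <- ifelse(summer, params$a * (1 + params$summer_maint_cut), params$a)
  b_z <- ifelse(summer, params$b * (1 + params$summer_bgw_boost), params$b)
  maintenance <- a_z * state$body_weight^0.75
  growth <- b_z * state$daily_gain
  aa_balance <- sf * aai
  cp <- maintenance + growth + aa_balance
  attr(cp, "components") <- data.frame(maintenance = maintenance,
                                       growth = growth,
                                       aa_balance = aa_balance + 0 * cp)
  cp
}

#' Feed energy-protein ratio
#'
#' @param me_density Feed ME density, kcal/kg.
#' @param cp_pct Crude protein concentration, % of diet (> 0).
#' @return Dimensionless ratio `me_density / cp_pct` (optimal interval
#'   125–135; see [check_ep_interval()]).
#' @export
#' @examples
#' energy_protein_ratio(2800, 22.4)  # 125
energy_protein_ratio <- function(me_density, cp_pct) {
  check_finite(me_density, "me_density")
  if (!is.numeric(cp_pct) || any(!is.finite(cp_pct)) || any(cp_pct <= 0))
    abort_invalid("cp_pct must be positive")
  me_density / cp_pct
}

#' Full daily requirement for one animal-day
#'
#' Orchestrates the requirement computation: classifies the season zone from
#' the ambient temperature, looks up the seasonal factor, computes the
#' lag-damped temperature adjustment, applies the breed's maintenance
#' multiplier and additive offset, derives the (seasonally adjusted)
#' amino-acid balance index from the diet — defaulting to a balanced index of
#' 1 when no diet is given — and evaluates both requirement equations.
#'
#' @param state A [duck_state()].
#' @param env An [env_conditions()].
#' @param breed A [breed_profile()] (default Cherry Valley baseline).
#' @param diet A [diet_spec()] or `NULL` (no diet: AAI defaults to 1 and no
#'   energy-protein ratio is reported).
#' @param params A [model_parameters()] object.
#' @param sf_on_maintenance Scale the maintenance energy term by the seasonal
#'   factor (default `TRUE`; set `FALSE` to keep the seasonal factor out of
#'   the energy equation and in the protein equation only).
#' @return An object of class `requirement_result` with fields `me` (kJ/d),
#'   `cp` (g/d), `ep_ratio` (NA without a diet), `zone`, and `components`
#'   (named breakdowns whose sums equal the totals).
#' @export
#' @examples
#' daily_requirement(duck_state(1.8, 42, age = 21), env_conditions(8, 3))
daily_requirement <- function(state, env, breed = builtin_profiles()$cherry_valley,
                              diet = NULL, params = model_parameters(),
                              sf_on_maintenance = TRUE) {
  zone <- classify_season(env$ambient_temp, params$t_low, params$t_high)
  sf <- seasonal_factor(zone, params$sf_table)
  w075 <- state$body_weight^0.75
  temp_adj <- temperature_adjustment(env, w075, params)
  mult <- breed_energy_multiplier(breed, zone)
  offset <- breed$bc + params$bc
  sf_m <- if (sf_on_maintenance) sf * mult else mult
  me <- compute_me(state, env_adjustment = temp_adj, sf_m = sf_m,
                   params = params, breed_offset = offset)
  aai <- if (is.null(diet)) 1 else
    compute_aai(diet$lysine_pct, diet$methionine_pct)
  aai_adj <- seasonal_aai_adjustment(aai, zone, breed$kappa)
  cp <- compute_cp(state, sf = sf, aai = aai_adj, params = params,
                   zone = zone)
  ep <- if (is.null(diet)) NA_real_ else
    energy_protein_ratio(diet$me_density, diet$cp_pct)
  structure(list(me = as.numeric(me), cp = as.numeric(cp), ep_ratio = ep,
                 zone = zone,
                 components = list(me = attr(me, "components"),
                                   cp = attr(cp, "components")),
                 aai = aai_adj, sf = sf),
            class = "requirement_result")
}

#' @export
print.requirement_result <- function(x, ...) {
  cat(sprintf("Daily requirement (%s zone): ME %.1f kJ/d, CP %.2f g/d",
              x$zone[1], x$me[1], x$cp[1]))
  if (!is.na(x$ep_ratio[1])) {
    cat(sprintf(", E:P ratio %.1f (%s)", x$ep_ratio[1],
                check_ep_interval(x$ep_ratio[1])))
  }
  cat("\n  ME components:",
      paste(sprintf("%s %.1f", names(x$components$me),
                    unlist(x$components$me[1, ])), collapse = ", "), "\n")
  cat("  CP components:",
      paste(sprintf("%s %.2f", names(x$components$cp),
                    unlist(x$components$cp[1, ])), collapse = ", "), "\n")
  invisible(x)
}

#' Vectorised requirement predictions for a flock table
#'
#' Evaluates the full model for every row of a flock record table (the same
#' arithmetic as [daily_requirement()], vectorised for calibration and batch
#' scoring). Rows may carry per-row diets via `lysine_pct`/`methionine_pct`
#' columns; rows without them use a balanced index of 1.
#'
#' @param obs Data frame with columns `weight_kg`, `bgw_g_per_d`, `et_c`,
#'   `cold_days` (computed from `et_c` per duck if absent) and `breed`;
#'   optionally `lysine_pct`, `methionine_pct`.
#' @param params A [model_parameters()] object.
#' @param registry Named list of breed profiles.
#' @param sf_on_maintenance See [daily_requirement()].
#' @return Data frame with columns `me`, `cp`, `zone`.
#' @export
predict_requirements <- function(obs, params = model_parameters(),
                                 registry = builtin_profiles(),
                                 sf_on_maintenance = TRUE) {
  obs <- ensure_cold_days(obs, params$t_low)
  zone <- classify_season(obs$et_c, params$t_low, params$t_high)
  sf <- seasonal_factor(zone, params$sf_table)
  w075 <- obs$weight_kg^0.75
  temp_adj <- temp_adjust_vec(obs$et_c, obs$cold_days, w075, params)
  eff <- effective_growth_coefficients(obs$bgw_g_per_d, params)

  breeds <- as.character(obs$breed)
  for (b in unique(breeds)) get_breed(b, registry)  # fail fast on unknowns
  lam_del <- vapply(registry, function(p) interaction_term(p$lambda, p$delta),
                    numeric(1))
  surch <- vapply(registry, function(p) p$winter_surcharge, numeric(1))
  kapp <- vapply(registry, function(p) p$kappa, numeric(1))
  bc_br <- vapply(registry, function(p) p$bc, numeric(1))
  mult <- unname(lam_del[breeds]) *
    ifelse(zone == "cold", 1 + unname(surch[breeds]), 1)
  offset <- unname(bc_br[breeds]) + params$bc

  sf_m <- if (sf_on_maintenance) sf * mult else mult
  me <- sf_m * eff$alpha * w075 + eff$beta * obs$bgw_g_per_d + temp_adj +
    offset

  aai <- rep(1, nrow(obs))
  if (all(c("lysine_pct", "methionine_pct") %in% names(obs))) {
    has_diet <- !is.na(obs$lysine_pct) & !is.na(obs$methionine_pct)
    if (any(has_diet))
      aai[has_diet] <- compute_aai(obs$lysine_pct[has_diet],
                                   obs$methionine_pct[has_diet])
  }
  aai <- seasonal_aai_adjustment(aai, zone, unname(kapp[breeds]))
  summer <- zone == "heat"
  a_z <- ifelse(summer, params$a * (1 + params$summer_maint_cut), params$a)
  b_z <- ifelse(summer, params$b * (1 + params$summer_bgw_boost), params$b)
  cp <- a_z * w075 + b_z * obs$bgw_g_per_d + sf * aai

  data.frame(me = me, cp = cp, zone = zone)
}

# Fill in the consecutive-cold-day column from the temperature series,
# scanning per duck (ordered by day) when grouping columns are present.
ensure_cold_days <- function(obs, t_low = 15) {
  if ("cold_days" %in% names(obs) && !anyNA(obs$cold_days)) return(obs)
  if ("duck_id" %in% names(obs)) {
    key <- if ("house_id" %in% names(obs))
      paste(obs$house_id, obs$duck_id) else as.character(obs$duck_id)
    ord <- order(key, obs$day)
    cd <- integer(nrow(obs))
    for (k in unique(key[ord])) {
      idx <- ord[key[ord] == k]
      cd[idx] <- consecutive_cold_days(obs$et_c[idx], t_low)
    }
    obs$cold_days <- cd
  } else {
    obs$cold_days <- consecutive_cold_days(obs$et_c, t_low)
  }
  obs
}
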