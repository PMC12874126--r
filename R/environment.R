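# Season-zone classification, seasonal factors and the temperature-lag
# compensation mechanism.

#' Ambient environment for one animal-day
#'
#' @param ambient_temp Ambient (house) temperature, °C.
#' @param consecutive_cold_days Number of successive days, counting the
#'   current one, with temperature below the lower thermoneutral limit.
#'   0 means no ongoing cold spell.
#' @param humidity Relative humidity, % (carried through but not used by the
#'   model; reserved for a humidity correction that is not parameterised).
#' @return An object of class `env_conditions`.
#' @export
#' @examples
#' env_conditions(8, consecutive_cold_days = 3)
env_conditions <- function(ambient_temp, consecutive_cold_days = 0L,
                           humidity = NA_real_) {
  check_finite(ambient_temp, "ambient_temp")
  if (!is.numeric(consecutive_cold_days) || any(consecutive_cold_days < 0) ||
      any(consecutive_cold_days != floor(consecutive_cold_days)))
    abort_invalid("consecutive_cold_days must be a non-negative integer")
  structure(list(ambient_temp = ambient_temp,
                 consecutive_cold_days = as.integer(consecutive_cold_days),
                 humidity = humidity),
            class = "env_conditions")
}

#' Classify a temperature into a season zone
#'
#' The thermoneutral band is the closed interval `[t_low, t_high]`; strictly
#' below it is `cold`, strictly above it `heat`. The defaults 15 and 28 °C
#' are the lower and upper thermoneutral limits for growing meat ducks.
#'
#' @param et Ambient temperature, °C (vectorised).
#' @param t_low,t_high Thermoneutral band limits, °C.
#' @return Character vector in `{"cold", "thermoneutral", "heat"}`.
#' @export
#' @examples
#' classify_season(c(10, 15, 20, 28, 30))
classify_season <- function(et, t_low = 15, t_high = 28) {
  check_finite(et, "et")
  if (t_low >= t_high) abort_invalid("t_low must be below t_high")
  ifelse(et < t_low, "cold", ifelse(et > t_high, "heat", "thermoneutral"))
}

#' Seasonal factor for a zone
#'
#' Multiplicative correction applied to maintenance requirements: winter
#' (cold) 1.35, spring/autumn (thermoneutral) 1.15, summer (heat) 1.05 by
#' default.
#'
#' @param zone Character vector of zones from [classify_season()].
#' @param sf_table Named numeric vector mapping zones to factors.
#' @return Numeric vector of multipliers.
#' @export
#' @examples
#' seasonal_factor("cold")
seasonal_factor <- function(zone,
                            sf_table = c(cold = 1.35, thermoneutral = 1.15,
                                         heat = 1.05)) {
  missing_zones <- setdiff(unique(zone), names(sf_table))
  if (length(missing_zones))
    abort_config("sf_table has no entry for zone(s): ",
                 paste(missing_zones, collapse = ", "))
  unname(sf_table[zone])
}

#' Temperature-lag damping coefficient
#'
#' During a sustained cold spell the behavioural response (extra feed intake)
#' falls increasingly short of the theoretical cold compensation. The damping
#' coefficient gamma is a left-closed step function of the number of
#' consecutive cold days n: 1 for n = 0, then 0.85 / 0.51 / 0.32 from the
#' breakpoints n = 1, 3, 5 onward (values beyond the last breakpoint keep its
#' value).
#'
#' @param n Integer vector of consecutive cold days (>= 0).
#' @param gamma_table Data frame with columns `n_min`, `gamma` (see
#'   [default_gamma_table()]).
#' @return Numeric vector of damping coefficients in (0, 1].
#' @export
#' @examples
#' lag_coefficient(c(0, 1, 2, 3, 5, 7))
lag_coefficient <- function(n, gamma_table = default_gamma_table()) {
  if (!is.numeric(n) || anyNA(n) || any(n < 0))
    abort_invalid("n must be a non-negative count of consecutive cold days")
  idx <- findInterval(n, gamma_table$n_min)
  ifelse(idx == 0, 1, gamma_table$gamma[pmax(idx, 1)])
}

#' Apply lag damping to a theoretical compensation
#'
#' @param theoretical_compensation Theoretical cold compensation, in percent
#'   or kJ/d (any linear unit).
#' @param gamma Damping coefficient in (0, 1], from [lag_coefficient()].
#' @return Damped compensation, same units as the input.
#' @export
#' @examples
#' apply_lag(60, lag_coefficient(5))  # 19.2
apply_lag <- function(theoretical_compensation, gamma) {
  if (!is.numeric(gamma) || anyNA(gamma) || any(gamma <= 0) || any(gamma > 1))
    abort_invalid("gamma must lie in (0, 1]")
  gamma * theoretical_compensation
}

#' Temperature adjustment to the energy requirement
#'
#' Deviation-from-threshold form of the temperature term: below the lower
#' thermoneutral limit the requirement grows by
#' `gamma(n) * k3_cold * (t_low - ET)` per unit metabolic weight (damped by
#' the cold-spell lag); above the upper limit it shrinks by
#' `k3_heat * (ET - t_high)` per unit metabolic weight (no lag — the damping
#' models under-response to sustained cold only); inside the band it is zero.
#' The adjustment is continuous in ET at both thresholds.
#'
#' @param env An [env_conditions()] object (fields may be vectors of equal
#'   length).
#' @param state_w075 Metabolic body weight, kg^0.75 (vectorised).
#' @param params A [model_parameters()] object.
#' @return Energy adjustment, kJ/d (positive in cold, negative in heat).
#' @export
#' @examples
#' temperature_adjustment(env_conditions(10), 1, model_parameters())
temperature_adjustment <- function(env, state_w075, params) {
  temp_adjust_vec(env$ambient_temp, env$consecutive_cold_days, state_w075,
                  params)
}

# Vectorised core shared with the bulk predictor.
temp_adjust_vec <- function(et, cold_days, w075, params) {
  gamma <- lag_coefficient(cold_days, params$gamma_table)
  cold <- gamma * params$k3_cold * pmax(0, params$t_low - et) * w075
  heat <- params$k3_heat * pmax(0, et - params$t_high) * w075
  cold - heat
}

#' Consecutive cold-day counts for a temperature series
#'
#' Scans a per-day temperature series and returns, for each day, the number
#' of immediately preceding days — counting the day itself — with temperature
#' strictly below `t_low`. Days at or above `t_low` reset the count to 0.
#'
#' @param et Numeric vector of daily temperatures, °C, in chronological order.
#' @param t_low Lower thermoneutral limit, °C.
#' @return Integer vector the same length as `et`.
#' @export
#' @examples
#' consecutive_cold_days(c(10, 12, 16, 9, 8, 8))  # 1 2 0 1 2 3
consecutive_cold_days <- function(et, t_low = 15) {
  check_finite(et, "et")
  n <- integer(length(et))
  run <- 0L
  for (i in seq_along(et)) {
    run <- if (et[i] < t_low) run + 1L else 0L
    n[i] <- run
  }
  n
}
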