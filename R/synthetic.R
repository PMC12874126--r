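# Seeded synthetic flock-data generator: Gompertz growth trajectories,
# seasonal temperature series and noisy requirement observations with the
# statistical structure the model assumes, so calibration and the full
# pipeline are testable without any external data.

#' Simulation configuration
#'
#' Defaults describe a commercial 42-day grow-out: 200 birds, Gompertz
#' growth to a 3.2-kg asymptote (rate 0.08/d, inflection day 18, 5 %
#' between-bird CV on the asymptote — the peak daily gain then exceeds the
#' 35 g/d rapid-growth threshold), a winter house scenario (mean 8 °C,
#' 3 °C day-to-day SD) and 5 % multiplicative observation noise on both
#' requirement targets.
#'
#' @param n_ducks Number of birds (>= 1).
#' @param n_days Days on feed (>= 1, default 42).
#' @param asymptotic_weight Gompertz asymptote A, kg (default 3.2).
#' @param growth_rate Gompertz rate k, 1/d (default 0.08).
#' @param inflection_day Gompertz inflection t_i, d (default 18).
#' @param heterogeneity_cv Between-bird lognormal CV on A (default 0.05).
#' @param scenario Season scenario: `"winter"` (mean 8 °C), `"summer"`
#'   (31 °C), `"transition"` (21 °C) or `"annual-sinusoid"` (19.5 °C ± 12 °C
#'   over a 365-day cycle, spanning all three zones).
#' @param temp_noise_sd Day-to-day Gaussian temperature SD, °C (default 3).
#' @param obs_noise_sd Multiplicative observation noise SD, fraction
#'   (default 0.05).
#' @param breed Breed label from the registry (default `"cherry_valley"`).
#' @param params True generating [model_parameters()].
#' @param seed Integer seed (mandatory; fixes every generated byte).
#' @return An object of class `simulation_config`.
#' @export
#' @examples
#' simulation_config(n_ducks = 5, seed = 1)
simulation_config <- function(n_ducks = 200, n_days = 42,
                              asymptotic_weight = 3.2, growth_rate = 0.08,
                              inflection_day = 18, heterogeneity_cv = 0.05,
                              scenario = c("winter", "summer", "transition",
                                           "annual-sinusoid"),
                              temp_noise_sd = 3, obs_noise_sd = 0.05,
                              breed = "cherry_valley",
                              params = model_parameters(), seed) {
  scenario <- match.arg(scenario)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 ||
      !is.finite(seed))
    abort_invalid("an integer seed is mandatory")
  if (n_ducks < 1 || n_days < 1)
    abort_invalid("n_ducks and n_days must be >= 1")
  if (asymptotic_weight <= 0 || growth_rate <= 0)
    abort_invalid("growth curve parameters must be positive")
  if (temp_noise_sd < 0 || obs_noise_sd < 0 || heterogeneity_cv < 0)
    abort_invalid("noise standard deviations must be >= 0")
  structure(list(n_ducks = as.integer(n_ducks), n_days = as.integer(n_days),
                 asymptotic_weight = asymptotic_weight,
                 growth_rate = growth_rate, inflection_day = inflection_day,
                 heterogeneity_cv = heterogeneity_cv, scenario = scenario,
                 temp_noise_sd = temp_noise_sd, obs_noise_sd = obs_noise_sd,
                 breed = breed, params = validate_parameters(params),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Gompertz curve W(t) = A exp(-exp(-k (t - t_i))).
gompertz_weight <- function(t, A, k, t_i) A * exp(-exp(-k * (t - t_i)))

#' Per-bird growth trajectories
#'
#' Gompertz live-weight curves with lognormal between-bird heterogeneity on
#' the asymptote (the draw is seeded from the config). Daily gain is the
#' first difference of weight, in g/d; under the default curve the peak gain
#' exceeds 35 g/d, so the rapid-growth coefficient reallocation is exercised.
#'
#' @param config A [simulation_config()].
#' @return Data frame with columns `duck_id`, `day`, `weight_kg`,
#'   `bgw_g_per_d`.
#' @export
growth_trajectory <- function(config) {
  set.seed(config$seed)
  cv <- config$heterogeneity_cv
  sdlog <- sqrt(log(1 + cv^2))
  A_i <- config$asymptotic_weight *
    stats::rlnorm(config$n_ducks, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  days <- seq_len(config$n_days)
  out <- do.call(rbind, lapply(seq_len(config$n_ducks), function(i) {
    w <- gompertz_weight(days, A_i[i], config$growth_rate,
                         config$inflection_day)
    w_prev <- gompertz_weight(days - 1, A_i[i], config$growth_rate,
                              config$inflection_day)
    data.frame(duck_id = i, day = days, weight_kg = w,
               bgw_g_per_d = (w - w_prev) * 1000)
  }))
  rownames(out) <- NULL
  out
}

#' House temperature series
#'
#' Daily ambient temperature: the scenario mean (winter 8 °C, summer 31 °C,
#' transition 21 °C, or an annual sinusoid 19.5 − 12 cos(2 pi day/365) °C)
#' plus Gaussian day-to-day noise, with the consecutive-cold-day count
#' derived by the documented scan ([consecutive_cold_days()]).
#'
#' @param config A [simulation_config()].
#' @return Data frame with columns `day`, `et_c`, `cold_days`.
#' @export
temperature_series <- function(config) {
  set.seed(config$seed + 1L)
  days <- seq_len(config$n_days)
  mean_temp <- switch(config$scenario,
    winter = rep(8, config$n_days),
    summer = rep(31, config$n_days),
    transition = rep(21, config$n_days),
    "annual-sinusoid" = 19.5 - 12 * cos(2 * pi * days / 365))
  et <- mean_temp + stats::rnorm(config$n_days, 0, config$temp_noise_sd)
  data.frame(day = days, et_c = et,
             cold_days = consecutive_cold_days(et, config$params$t_low))
}

#' Generate a noisy flock observation set
#'
#' Composes the growth trajectories with the (house-level, shared) daily
#' temperature series, evaluates the true model requirement for every
#' animal-day at the config's true parameters, and perturbs both targets with
#' independent multiplicative Gaussian noise:
#' `observed = true * (1 + eps)`, `eps ~ N(0, obs_noise_sd)`. The whole
#' output is a deterministic function of the config (including the seed).
#'
#' @param config A [simulation_config()].
#' @param csv_path Optional path: write the generated records as a flock CSV
#'   (same schema [read_flock_csv()] reads; round-trip safe).
#' @param registry Breed registry supplying the config's breed.
#' @return An [as_observation_set()] data frame (provenance `"synthetic"`)
#'   with the flock-record columns plus `observed_me_kj`, `observed_cp_g`
#'   and the noise-free `true_me_kj`, `true_cp_g`.
#' @export
#' @examples
#' obs <- generate_observations(simulation_config(n_ducks = 3, seed = 42))
#' head(obs)
generate_observations <- function(config, csv_path = NULL,
                                  registry = builtin_profiles()) {
  get_breed(config$breed, registry)
  growth <- growth_trajectory(config)
  temps <- temperature_series(config)
  obs <- merge(growth, temps, by = "day", sort = FALSE)
  obs <- obs[order(obs$duck_id, obs$day), ]
  rownames(obs) <- NULL
  obs$house_id <- "H1"
  obs$breed <- config$breed
  truth <- predict_requirements(obs, config$params, registry)
  set.seed(config$seed + 2L)
  n <- nrow(obs)
  eps_me <- stats::rnorm(n, 0, config$obs_noise_sd)
  eps_cp <- stats::rnorm(n, 0, config$obs_noise_sd)
  obs$true_me_kj <- truth$me
  obs$true_cp_g <- truth$cp
  obs$observed_me_kj <- truth$me * (1 + eps_me)
  obs$observed_cp_g <- truth$cp * (1 + eps_cp)
  obs <- obs[, c("house_id", "duck_id", "day", "weight_kg", "bgw_g_per_d",
                 "et_c", "cold_days", "breed", "observed_me_kj",
                 "observed_cp_g", "true_me_kj", "true_cp_g")]
  obs <- as_observation_set(obs, "synthetic")
  if (!is.null(csv_path)) write_flock_csv(obs, csv_path)
  obs
}
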