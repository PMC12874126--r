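# Shared fixtures: small synthetic observation sets built in code.

default_truth <- function() model_parameters()

small_config <- function(n_ducks = 10, n_days = 42, noise = 0,
                         scenario = "winter", seed = 101,
                         params = model_parameters(), ...) {
  simulation_config(n_ducks = n_ducks, n_days = n_days,
                    obs_noise_sd = noise, scenario = scenario,
                    seed = seed, params = params, ...)
}

small_obs <- function(...) generate_observations(small_config(...))

# A minimal hand-built flock frame (3 rows, thermoneutral).
tiny_flock <- function() {
  data.frame(house_id = "H1", duck_id = c(1, 1, 2), day = c(1, 2, 1),
             weight_kg = c(1.0, 1.05, 0.9), bgw_g_per_d = c(40, 50, 30),
             et_c = 20, breed = "cherry_valley",
             observed_me_kj = c(900, 950, 800),
             observed_cp_g = c(15, 16, 13))
}
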