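# Core requirement equations: growth-stage coefficient reallocation, the
# energy and protein factorial equations, and the daily orchestrator.

test_that("growth coefficients pass through below the rapid-growth threshold", {
  p <- model_parameters()
  eff <- effective_growth_coefficients(0, p)
  expect_identical(eff$alpha, p$alpha)
  expect_identical(eff$beta, p$beta)
  # idempotence: feeding an already-adjusted pair back in at low gain
  p2 <- model_parameters(alpha = eff$alpha, beta = eff$beta)
  eff2 <- effective_growth_coefficients(10, p2)
  expect_identical(eff2$alpha, eff$alpha)
  expect_identical(eff2$beta, eff$beta)
})

test_that("rapid growth reallocates -18 % alpha / +24 % beta", {
  p <- model_parameters(alpha = 100, beta = 10)
  eff <- effective_growth_coefficients(40, p)
  expect_equal(eff$alpha, 82.0)
  expect_equal(eff$beta, 12.4)
  # the published conventional-growth weight pair (0.62, 0.38) maps to
  # (0.5084, 0.4712): allocation ratio moves from 1.63 toward parity
  pw <- model_parameters(alpha = 0.62, beta = 0.38)
  effw <- effective_growth_coefficients(40, pw)
  expect_equal(effw$alpha, 0.62 * 0.82, tolerance = 1e-12)
  expect_equal(effw$beta, 0.38 * 1.24, tolerance = 1e-12)
  expect_equal(round_half_up(pw$alpha / pw$beta, 2), 1.63)
  expect_equal(round_half_up(effw$alpha / effw$beta, 2), 1.08)
  expect_error(effective_growth_coefficients(-1, p), "bgw")
})

test_that("compute_me reproduces hand arithmetic and the winter worked example", {
  p <- model_parameters()
  # winter maintenance of a 1-kg bird: 541.7 * 1.35 = 731.3 to 1 d.p.
  me <- compute_me(duck_state(1, 0), env_adjustment = 0, sf_m = 1.35,
                   params = p)
  expect_equal(round_half_up(as.numeric(me), 1), 731.3)
  # baseline identity
  expect_equal(as.numeric(compute_me(duck_state(1, 0), 0, 1, p)), 541.7)
  # hand-arithmetic oracle with growth, environment and offset terms
  me2 <- compute_me(duck_state(2.297, 30), env_adjustment = 50, sf_m = 1,
                    params = p, breed_offset = 10)
  expect_equal(as.numeric(me2), 541.7 * 2.297^0.75 + 19.86 * 30 + 60,
               tolerance = 1e-12)
  # 1666.6 when computed via the 4-digit metabolic weight 1.866; exact
  # arithmetic gives 1666.49, so allow the intermediate-rounding slack
  expect_lt(abs(as.numeric(me2) - 1666.6), 0.15)
  expect_error(compute_me(duck_state(1, 0), env_adjustment = NaN, params = p),
               "finite")
  expect_error(compute_me(duck_state(1, 0), sf_m = 0, params = p), "sf_m")
})

test_that("compute_me component breakdown sums to the total", {
  p <- model_parameters()
  me <- compute_me(duck_state(c(1, 2.3), c(10, 50)), env_adjustment = c(0, 30),
                   sf_m = 1.15, params = p, breed_offset = 5)
  comp <- attr(me, "components")
  expect_equal(rowSums(comp), as.numeric(me), tolerance = 1e-9)
})

test_that("compute_cp applies the seasonal modifiers and sums components", {
  p <- model_parameters(a = 6, b = 0.18)
  cp <- compute_cp(duck_state(1, 20), sf = 1.15, aai = 1.07, params = p,
                   zone = "thermoneutral")
  expect_equal(as.numeric(cp), 6 + 3.6 + 1.2305, tolerance = 1e-12)
  comp <- attr(cp, "components")
  expect_equal(rowSums(comp), as.numeric(cp), tolerance = 1e-9)
  # heat zone: maintenance cut 18 %, growth boosted 23 %
  cph <- compute_cp(duck_state(1, 20), sf = 1.05, aai = 1, params = p,
                    zone = "heat")
  expect_equal(as.numeric(cph), 6 * 0.82 + 0.18 * 1.23 * 20 + 1.05,
               tolerance = 1e-12)
  # degenerate tiny bird at zero gain: the SF*AAI term alone survives
  cp0 <- compute_cp(duck_state(1e-12, 0), sf = 1, aai = 1, params = p)
  expect_equal(as.numeric(cp0), 1.0, tolerance = 1e-8)
  expect_error(compute_cp(duck_state(1, 0), sf = -1, aai = 1, params = p),
               "sf")
  expect_error(compute_cp(duck_state(1, 0), sf = 1, aai = 0, params = p),
               "aai")
})

test_that("ME is strictly increasing in weight and in daily gain", {
  p <- model_parameters()
  w <- seq(0.2, 3.2, by = 0.2)
  me_w <- as.numeric(compute_me(duck_state(w, 20), 0, 1.15, p))
  expect_true(all(diff(me_w) > 0))
  g <- seq(0, 90, by = 5)
  me_g <- as.numeric(compute_me(duck_state(1.5, g), 0, 1.15, p))
  expect_true(all(diff(me_g) > 0))
})

test_that("energy_protein_ratio is division with guarded input", {
  expect_equal(energy_protein_ratio(2800, 22.4), 125)
  expect_equal(energy_protein_ratio(2730, 21), 130)
  expect_equal(energy_protein_ratio(2950, 2950), 1)
  expect_error(energy_protein_ratio(2800, 0), "cp_pct")
})

test_that("daily_requirement composes the sub-modules faithfully", {
  p <- model_parameters()
  state <- duck_state(1.8, 42, age = 21)
  # thermoneutral: zero temperature component, transition SF 1.15
  res <- daily_requirement(state, env_conditions(20), params = p)
  expect_equal(res$zone, "thermoneutral")
  expect_equal(res$sf, 1.15)
  expect_equal(res$components$me$temperature, 0)
  # compositional oracle: me equals compute_me with independently computed terms
  env <- env_conditions(8, consecutive_cold_days = 3)
  breed <- builtin_profiles()$muscovy
  res2 <- daily_requirement(state, env, breed = breed, params = p)
  zone <- classify_season(8, p$t_low, p$t_high)
  sf <- seasonal_factor(zone, p$sf_table)
  adj <- temperature_adjustment(env, 1.8^0.75, p)
  mult <- breed_energy_multiplier(breed, zone)
  me_oracle <- compute_me(state, env_adjustment = adj, sf_m = sf * mult,
                          params = p, breed_offset = breed$bc)
  expect_equal(res2$me, as.numeric(me_oracle), tolerance = 1e-12)
  aai <- seasonal_aai_adjustment(1, zone, breed$kappa)
  cp_oracle <- compute_cp(state, sf, aai, p, zone)
  expect_equal(res2$cp, as.numeric(cp_oracle), tolerance = 1e-12)
  # component sums reproduce the totals
  expect_equal(rowSums(res2$components$me), res2$me, tolerance = 1e-9)
  expect_equal(rowSums(res2$components$cp), res2$cp, tolerance = 1e-9)
  # determinism: identical calls, identical results
  expect_identical(daily_requirement(state, env, breed = breed, params = p),
                   res2)
})

test_that("daily_requirement reports the diet's energy-protein ratio", {
  d <- diet_spec(2730, 21, 0.9, 0.3)
  res <- daily_requirement(duck_state(1.8, 42), env_conditions(20), diet = d)
  expect_equal(res$ep_ratio, 130)
  expect_equal(check_ep_interval(res$ep_ratio), "optimal")
  res_no <- daily_requirement(duck_state(1.8, 42), env_conditions(20))
  expect_true(is.na(res_no$ep_ratio))
})

test_that("predict_requirements matches daily_requirement row by row", {
  obs <- small_obs(n_ducks = 3, n_days = 20, scenario = "annual-sinusoid")
  p <- model_parameters()
  pred <- predict_requirements(obs, p)
  for (i in c(1, 7, 35)) {
    res <- daily_requirement(
      duck_state(obs$weight_kg[i], obs$bgw_g_per_d[i]),
      env_conditions(obs$et_c[i], obs$cold_days[i]),
      breed = get_breed(obs$breed[i]), params = p)
    expect_equal(pred$me[i], res$me, tolerance = 1e-12)
    expect_equal(pred$cp[i], res$cp, tolerance = 1e-12)
    expect_equal(pred$zone[i], res$zone)
  }
})

test_that("duck_state rejects non-physical values", {
  expect_error(duck_state(0, 10), "body_weight")
  expect_error(duck_state(1, -1), "daily_gain")
  expect_error(duck_state(1, 10, age = -1), "age")
})
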