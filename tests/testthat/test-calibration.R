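# Residual construction, the two fitters, and the error metrics.

test_that("residuals vanish at the generating parameters on noise-free data", {
  obs <- small_obs(noise = 0, seed = 11)
  r <- requirement_residuals(model_parameters(), obs)
  expect_equal(max(abs(r)), 0)
})

test_that("residuals are standardised by the observed spread", {
  obs <- tiny_flock()
  p <- model_parameters()
  pred <- predict_requirements(obs, p)
  r <- requirement_residuals(p, obs, targets = "me")
  expect_equal(unname(r),
               (pred$me - obs$observed_me_kj) / sd(obs$observed_me_kj),
               tolerance = 1e-12)
  # a single hand case: prediction 100 vs observation 90 with sd 10
  expect_equal(unname((100 - 90) / 10), 1)
  # zero-variance target is a configuration error
  obs2 <- tiny_flock()
  obs2$observed_cp_g <- 15
  expect_error(requirement_residuals(p, obs2, targets = "cp"),
               "zero variance")
})

test_that("duplicating every observation leaves the refit unchanged", {
  obs <- small_obs(n_ducks = 5, noise = 0.05, seed = 21)
  init <- model_parameters(alpha = 600, beta = 17)
  fit1 <- fit_lm(obs, init, free = c("alpha", "beta"))
  obs2 <- as_observation_set(rbind(as.data.frame(obs), as.data.frame(obs)),
                             "synthetic")
  fit2 <- fit_lm(obs2, init, free = c("alpha", "beta"))
  expect_equal(fit2$estimates, fit1$estimates, tolerance = 1e-6)
  # residual distribution is unchanged up to the (n-1)-denominator sd shift
  r1 <- requirement_residuals(fit1$parameters, obs)
  r2 <- requirement_residuals(fit2$parameters, obs2)
  expect_equal(length(r2), 2L * length(r1))
  scale_shift <- sd(rep(obs$observed_me_kj, 2)) / sd(obs$observed_me_kj)
  r2_me <- r2[grepl("^me", names(r2))] * scale_shift
  expect_equal(unname(sort(r2_me)),
               unname(sort(rep(r1[grepl("^me", names(r1))], 2))),
               tolerance = 1e-6)
})

test_that("damped least squares recovers generating parameters exactly on noise-free data", {
  truth <- model_parameters()
  obs <- small_obs(n_ducks = 15, noise = 0, seed = 31)
  init <- model_parameters(alpha = truth$alpha * 1.2, beta = truth$beta * 0.8,
                           k3_cold = truth$k3_cold * 1.2)
  fit <- fit_lm(obs, init, free = c("alpha", "beta", "k3_cold"))
  expect_true(fit$converged)
  expected <- c(alpha = truth$alpha, beta = truth$beta,
                k3_cold = truth$k3_cold)
  expect_equal(fit$estimates, expected, tolerance = 1e-3)
  rel <- abs(fit$estimates - expected) / expected
  expect_true(all(rel < 0.001))
})

test_that("an empty free set returns the init unchanged and converged", {
  obs <- tiny_flock()
  fit <- fit_lm(obs, model_parameters(), free = character(0))
  expect_true(fit$converged)
  expect_equal(fit$iterations, 0L)
  expect_equal(fit$parameters, model_parameters())
})

test_that("fit cost never exceeds the cost at the starting point", {
  for (s in 1:3) {
    obs <- small_obs(n_ducks = 4, noise = 0.1, seed = 40 + s)
    init <- model_parameters(alpha = 450, beta = 25)
    fit <- fit_lm(obs, init, free = c("alpha", "beta"))
    cost0 <- sum(requirement_residuals(init, obs)^2)
    cost1 <- sum(requirement_residuals(fit$parameters, obs)^2)
    expect_lte(cost1, cost0)
  }
})

test_that("one-parameter fit agrees with a dense grid search and with nls.lm", {
  obs <- small_obs(n_ducks = 2, noise = 0.05, seed = 51)
  init <- model_parameters(beta = 15)
  fit <- fit_lm(obs, init, free = "beta", targets = "me")
  grid <- seq(15, 25, length.out = 1e4)
  step <- grid[2] - grid[1]
  cost <- vapply(grid, function(b) {
    sum(requirement_residuals(model_parameters(beta = b), obs,
                              targets = "me")^2)
  }, numeric(1))
  best <- grid[which.min(cost)]
  expect_lt(abs(fit$estimates[["beta"]] - best), step)
  # independent damped-least-squares implementation agrees
  nl <- minpack.lm::nls.lm(
    par = list(beta = 15),
    fn = function(par) {
      requirement_residuals(model_parameters(beta = par$beta), obs,
                            targets = "me")
    })
  expect_equal(fit$estimates[["beta"]], coef(nl)[["beta"]],
               tolerance = 1e-6)
})

test_that("unidentifiable free sets trigger a rank warning", {
  obs <- small_obs(n_ducks = 3, noise = 0, seed = 61,
                   scenario = "transition")
  # thermoneutral-only data carry no information about the cold coefficient
  expect_warning(fit_lm(obs, model_parameters(), free = c("beta", "k3_cold"),
                        max_iter = 2),
                 "identifiable")
})

test_that("gradient descent honours its schedule and recovers on noise-free data", {
  truth <- model_parameters()
  obs <- small_obs(n_ducks = 10, noise = 0, seed = 71)
  init <- model_parameters(alpha = truth$alpha * 1.15, beta = truth$beta * 0.85)
  fit <- fit_gd(obs, init, free = c("alpha", "beta"),
                lr0 = 0.05, decay = 0.999, epochs = 400)
  expected <- c(alpha = truth$alpha, beta = truth$beta)
  rel <- abs(fit$estimates - expected) / expected
  expect_true(all(rel < 0.01))
  # looser than the damped least-squares fit on the same data
  fit_ref <- fit_lm(obs, init, free = c("alpha", "beta"))
  rel_ref <- abs(fit_ref$estimates - expected) / expected
  expect_true(all(rel_ref <= rel + 1e-12))
})

test_that("decay = 1 reduces to fixed-step descent with non-increasing convex cost", {
  obs <- small_obs(n_ducks = 5, noise = 0.05, seed = 81)
  init <- model_parameters(beta = 16)
  fit <- fit_gd(obs, init, free = "beta", lr0 = 0.01, decay = 1,
                epochs = 50, targets = "me")
  expect_equal(fit$final_control[["learning_rate"]], 0.01)
  # beta enters the residuals linearly, so the cost is convex in beta
  expect_true(all(diff(fit$trace$cost) <= 1e-12))
})

test_that("divergent gradient descent aborts with a diagnostic", {
  obs <- small_obs(n_ducks = 3, noise = 0.05, seed = 91)
  expect_error(fit_gd(obs, model_parameters(), free = c("alpha", "beta"),
                      lr0 = 50, decay = 1, epochs = 100),
               "diverged")
})

test_that("rmse follows its definition and is permutation invariant", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 1), c(0, 2)), 1)
  set.seed(5)
  a <- rnorm(50)
  b <- rnorm(50)
  idx <- sample(50)
  expect_equal(rmse(a[idx], b[idx]), rmse(a, b))
  expect_error(rmse(1:3, 1:4), "equal length")
  # the published weight-ratio improvement 0.24 -> 0.18 is arithmetically 25 %
  expect_equal(error_reduction(0.24, 0.18), 25)
})

test_that("error_reduction reports integer-rounded percentages", {
  expect_equal(error_reduction(18, 6), 67)
  expect_equal(error_reduction(22, 18.9), 14)
  expect_equal(error_reduction(7, 7), 0)
  expect_error(error_reduction(0, 1), "positive")
  expect_error(error_reduction(1, -1), ">= 0")
})

test_that("fit reports serialise to YAML and JSON", {
  obs <- tiny_flock()
  fit <- fit_lm(obs, model_parameters(), free = "beta", max_iter = 5)
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_fit_report(fit, path)
    back <- if (ext == "json") jsonlite::read_json(path) else
      yaml::read_yaml(path)
    expect_equal(back$method, "levenberg-marquardt")
    expect_equal(as.numeric(back$estimates$beta), fit$estimates[["beta"]],
                 tolerance = 1e-8)
    unlink(path)
  }
})
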