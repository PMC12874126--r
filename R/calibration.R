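# Fit model coefficients to observed flock records: standardised-residual
# stacking across the two targets, damped least squares (Levenberg-Marquardt)
# and decaying-learning-rate gradient descent, plus error metrics.

FREE_PARAMETER_NAMES <- c("alpha", "beta", "k3_cold", "k3_heat", "a", "b", "bc")

#' Construct an observation set
#'
#' Validates a flock record table carrying observed requirements and tags its
#' provenance. An observation set is a plain data frame with (at least)
#' columns `weight_kg`, `bgw_g_per_d`, `et_c`, `breed`, `observed_me_kj`,
#' `observed_cp_g`, and optionally `house_id`, `duck_id`, `day`,
#' `cold_days`, `humidity_pct`, `lysine_pct`, `methionine_pct`.
#'
#' @param df Data frame of per-animal-day records.
#' @param provenance `"synthetic"` or `"file"`.
#' @return The validated data frame with class `observation_set` and a
#'   `provenance` attribute.
#' @export
as_observation_set <- function(df, provenance = c("file", "synthetic")) {
  provenance <- match.arg(provenance)
  required <- c("weight_kg", "bgw_g_per_d", "et_c", "breed")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    abort_schema("observation set missing column(s): ",
                 paste(missing_cols, collapse = ", "))
  if (nrow(df) < 1) abort_invalid("observation set must have at least 1 row")
  for (col in c("observed_me_kj", "observed_cp_g"))
    if (col %in% names(df) &&
        (any(!is.finite(df[[col]])) || any(df[[col]] <= 0)))
      abort_invalid(col, " must be positive and finite")
  structure(df, class = c("observation_set", "data.frame"),
            provenance = provenance)
}

#' Standardised prediction residuals
#'
#' Concatenates (predicted − observed) for each requested target, each
#' divided by the standard deviation of that target's observations so the
#' energy (kJ/d) and protein (g/d) scales are commensurate in a joint fit.
#'
#' @param params A [model_parameters()] object.
#' @param obs An [as_observation_set()] data frame with `observed_me_kj`
#'   and/or `observed_cp_g` columns.
#' @param targets Character subset of `c("me", "cp")`.
#' @param registry Breed registry (default built-ins).
#' @return Named numeric vector of standardised residuals (`me.*`, `cp.*`).
#' @export
requirement_residuals <- function(params, obs, targets = c("me", "cp"),
                                  registry = builtin_profiles()) {
  targets <- match.arg(targets, several.ok = TRUE)
  if (nrow(obs) < 1) abort_invalid("obs must be non-empty")
  pred <- predict_requirements(obs, params, registry)
  out <- numeric(0)
  for (tg in targets) {
    ocol <- if (tg == "me") "observed_me_kj" else "observed_cp_g"
    if (!ocol %in% names(obs))
      abort_schema("obs has no '", ocol, "' column for target '", tg, "'")
    observed <- obs[[ocol]]
    s <- stats::sd(observed)
    if (!is.finite(s) || s == 0)
      abort_config("target '", tg, "' has zero variance; cannot standardise")
    r <- (pred[[tg]] - observed) / s
    names(r) <- paste0(tg, ".", seq_along(r))
    out <- c(out, r)
  }
  out
}

# Residuals as a function of the free coefficient vector theta.
resid_fun <- function(theta, free, init, obs, targets, registry) {
  p <- set_parameters(init, stats::setNames(theta, free))
  requirement_residuals(p, obs, targets, registry)
}

# Finite-difference Jacobian of the residual vector at theta.
resid_jacobian <- function(theta, free, init, obs, targets, registry) {
  r0 <- resid_fun(theta, free, init, obs, targets, registry)
  J <- matrix(0, length(r0), length(theta),
              dimnames = list(NULL, free))
  for (j in seq_along(theta)) {
    h <- max(1e-6, 1e-6 * abs(theta[j]))
    tp <- tm <- theta
    tp[j] <- theta[j] + h
    tm[j] <- theta[j] - h
    rp <- try(resid_fun(tp, free, init, obs, targets, registry),
              silent = TRUE)
    rm <- try(resid_fun(tm, free, init, obs, targets, registry),
              silent = TRUE)
    if (inherits(rp, "try-error") || inherits(rm, "try-error")) {
      # one-sided fallback at a parameter-validity boundary
      if (inherits(rp, "try-error")) {
        J[, j] <- (r0 - rm) / h
      } else {
        J[, j] <- (rp - r0) / h
      }
    } else {
      J[, j] <- (rp - rm) / (2 * h)
    }
  }
  J
}

check_free_set <- function(free) {
  bad <- setdiff(free, FREE_PARAMETER_NAMES)
  if (length(bad))
    abort_invalid("free parameters must be among {",
                  paste(FREE_PARAMETER_NAMES, collapse = ", "),
                  "}; got: ", paste(bad, collapse = ", "))
  free
}

fit_result <- function(params, estimates, obs, registry, iterations,
                       converged, final_control, method, trace) {
  pred <- predict_requirements(obs, params, registry)
  per_target <- c(
    me = if ("observed_me_kj" %in% names(obs))
      rmse(pred$me, obs$observed_me_kj) else NA_real_,
    cp = if ("observed_cp_g" %in% names(obs))
      rmse(pred$cp, obs$observed_cp_g) else NA_real_)
  structure(list(parameters = params, estimates = estimates,
                 rmse = per_target, iterations = iterations,
                 converged = converged, final_control = final_control,
                 method = method, trace = trace),
            class = "duck_fit")
}

#' @export
print.duck_fit <- function(x, ...) {
  cat(sprintf("<duck_fit> %s: %s after %d iteration(s)\n", x$method,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  if (length(x$estimates)) {
    cat("  estimates:",
        paste(sprintf("%s = %.6g", names(x$estimates), x$estimates),
              collapse = ", "), "\n")
  }
  cat(sprintf("  RMSE: ME %.4g kJ/d, CP %.4g g/d;  final %s = %.3g\n",
              x$rmse[["me"]], x$rmse[["cp"]],
              names(x$final_control), x$final_control))
  invisible(x)
}

#' Fit free coefficients by damped least squares (Levenberg-Marquardt)
#'
#' Minimises the summed squared standardised residuals over the chosen free
#' coefficients. Each iteration solves the damped normal equations
#' `(J'J + damping * diag(J'J)) step = -J'r`; an accepted step divides the
#' damping by 10, a rejected one multiplies it by 10 (Marquardt's schedule,
#' initial damping 1e-3). Iteration stops when the relative cost change of an
#' accepted step falls below `tol` or after `max_iter` iterations; singular
#' normal equations fall back to a larger damping, and failure to find any
#' acceptable step is reported as non-convergence rather than an error. A
#' rank check of the Jacobian at the starting point warns when the free set
#' is not identifiable from the data's breed/temperature diversity.
#'
#' @param obs An observation set (see [as_observation_set()]).
#' @param init Starting [model_parameters()].
#' @param free Character vector naming the coefficients to fit, a subset of
#'   `alpha, beta, k3_cold, k3_heat, a, b, bc`.
#' @param max_iter Iteration cap (default 200).
#' @param tol Relative cost-change tolerance (default 1e-8).
#' @param targets Which observed targets to fit (`"me"`, `"cp"` or both).
#' @param registry Breed registry.
#' @return A `duck_fit` with fitted parameters, per-target RMSE, iteration
#'   count, convergence flag and the final damping value.
#' @export
fit_lm <- function(obs, init = model_parameters(),
                   free = c("alpha", "beta"), max_iter = 200, tol = 1e-8,
                   targets = c("me", "cp"), registry = builtin_profiles()) {
  check_free_set(free)
  if (length(free) == 0) {
    return(fit_result(init, stats::setNames(numeric(0), character(0)), obs,
                      registry, 0L, TRUE, c(damping = 1e-3), "levenberg-marquardt",
                      data.frame(iteration = integer(0), cost = numeric(0))))
  }
  theta <- vapply(free, function(nm) init[[nm]], numeric(1))
  r <- resid_fun(theta, free, init, obs, targets, registry)
  cost <- sum(r^2)
  trace <- data.frame(iteration = 0L, cost = cost)

  J0 <- resid_jacobian(theta, free, init, obs, targets, registry)
  if (qr(J0)$rank < length(free))
    warning("free parameter set not identifiable from these data ",
            "(rank-deficient Jacobian at the starting point)", call. = FALSE)

  damping <- 1e-3
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- resid_jacobian(theta, free, init, obs, targets, registry)
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    accepted <- FALSE
    while (!accepted && damping <= 1e12) {
      A <- JtJ + damping * diag(diag(JtJ) + 1e-12, length(free))
      step <- try(solve(A, -g), silent = TRUE)
      if (!inherits(step, "try-error")) {
        cand <- theta + as.numeric(step)
        r_new <- try(resid_fun(cand, free, init, obs, targets, registry),
                     silent = TRUE)
        if (!inherits(r_new, "try-error")) {
          cost_new <- sum(r_new^2)
          if (is.finite(cost_new) && cost_new < cost) {
            rel_change <- (cost - cost_new) / max(cost, .Machine$double.eps)
            theta <- cand
            r <- r_new
            cost <- cost_new
            damping <- max(damping / 10, 1e-12)
            accepted <- TRUE
            trace <- rbind(trace, data.frame(iteration = iter, cost = cost))
            if (rel_change < tol) converged <- TRUE
          }
        }
      }
      if (!accepted) damping <- damping * 10
    }
    if (!accepted) break     # no acceptable step at maximal damping
    if (converged) break
  }
  params <- set_parameters(init, stats::setNames(theta, free))
  fit_result(params, stats::setNames(theta, free), obs, registry, iter,
             converged, c(damping = damping), "levenberg-marquardt", trace)
}

#' Fit free coefficients by decaying-learning-rate gradient descent
#'
#' Full-batch gradient descent on half the mean squared standardised
#' residual, with the learning-rate schedule `lr0 * decay^epoch` (defaults
#' 0.001 and 0.95). Coefficients are updated on a relative scale (each step
#' is expressed in units of `max(|initial value|, 1)`) so a single learning
#' rate serves coefficients of very different magnitudes. The run aborts with
#' a diagnostic if the cost increases for 10 consecutive epochs. Given
#' identical inputs the trajectory is deterministic; `seed` only controls the
#' (optional) row shuffling and is logged with the result.
#'
#' @inheritParams fit_lm
#' @param lr0 Initial learning rate (> 0, default 0.001).
#' @param decay Multiplicative learning-rate decay per epoch, in (0, 1]
#'   (default 0.95; 1 gives fixed-step descent).
#' @param epochs Number of epochs (default 500).
#' @param seed Integer seed controlling optional row shuffling.
#' @param shuffle Shuffle row order each epoch (no effect on the full-batch
#'   gradient; retained for schedule compatibility).
#' @return A `duck_fit` with the final learning rate in `final_control`.
#' @export
fit_gd <- function(obs, init = model_parameters(),
                   free = c("alpha", "beta"), lr0 = 0.001, decay = 0.95,
                   epochs = 500, seed = 20260112, shuffle = FALSE,
                   targets = c("me", "cp"), registry = builtin_profiles()) {
  check_free_set(free)
  if (!is.finite(lr0) || lr0 <= 0) abort_invalid("lr0 must be positive")
  if (!is.finite(decay) || decay <= 0 || decay > 1)
    abort_invalid("decay must lie in (0, 1]")
  if (length(free) == 0) {
    return(fit_result(init, stats::setNames(numeric(0), character(0)), obs,
                      registry, 0L, TRUE, c(learning_rate = lr0),
                      "gradient-descent",
                      data.frame(epoch = integer(0), cost = numeric(0))))
  }
  theta0 <- vapply(free, function(nm) init[[nm]], numeric(1))
  scale <- pmax(abs(theta0), 1)
  n_res <- NULL
  cost_at <- function(theta) {
    r <- resid_fun(theta, free, init, obs, targets, registry)
    if (is.null(n_res)) n_res <<- length(r)
    0.5 * mean(r^2)
  }
  grad_at <- function(theta) {
    J <- resid_jacobian(theta, free, init, obs, targets, registry)
    r <- resid_fun(theta, free, init, obs, targets, registry)
    as.numeric(crossprod(J, r)) / length(r) * scale
  }
  set.seed(seed %% .Machine$integer.max)
  theta <- theta0
  cost <- cost_at(theta)
  trace <- data.frame(epoch = 0L, cost = cost)
  best_theta <- theta
  best_cost <- cost
  bad_run <- 0L
  lr <- lr0
  e <- 0L
  while (e < epochs) {
    e <- e + 1L
    lr <- lr0 * decay^(e - 1L)
    if (shuffle) obs <- obs[sample.int(nrow(obs)), , drop = FALSE]
    g <- grad_at(theta)
    cand <- theta - lr * g * scale
    cost_new <- try(cost_at(cand), silent = TRUE)
    if (inherits(cost_new, "try-error") || !is.finite(cost_new)) {
      bad_run <- bad_run + 1L
      cost_new <- Inf
    } else {
      theta <- cand
      if (cost_new > cost) bad_run <- bad_run + 1L else bad_run <- 0L
      cost <- cost_new
      if (cost < best_cost) {
        best_cost <- cost
        best_theta <- theta
      }
    }
    trace <- rbind(trace, data.frame(epoch = e, cost = cost))
    if (bad_run >= 10L)
      abort_config("gradient descent diverged: cost increased for 10 ",
                   "consecutive epochs (epoch ", e, ", lr ", signif(lr, 3),
                   "); reduce lr0")
  }
  params <- set_parameters(init, stats::setNames(best_theta, free))
  fit_result(params, stats::setNames(best_theta, free), obs, registry, e,
             TRUE, c(learning_rate = lr), "gradient-descent", trace)
}

#' Root mean squared error
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
#' @examples
#' rmse(c(1, 1), c(0, 2))  # 1
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 1)
    abort_invalid("predicted and observed must have equal length >= 1")
  sqrt(mean((predicted - observed)^2))
}

#' Relative error reduction, percent
#'
#' `100 * (err_traditional - err_dynamic) / err_traditional`, rounded
#' half-up to the nearest integer for reporting (so 14.09 % prints as 14).
#'
#' @param err_traditional Baseline error (> 0).
#' @param err_dynamic Comparison error (>= 0).
#' @return Integer-rounded percentage (negative if the comparison is worse).
#' @export
#' @examples
#' error_reduction(18, 6)     # 67
#' error_reduction(22, 18.9)  # 14
error_reduction <- function(err_traditional, err_dynamic) {
  if (!is.numeric(err_traditional) || any(err_traditional <= 0))
    abort_invalid("err_traditional must be positive")
  if (!is.numeric(err_dynamic) || any(err_dynamic < 0))
    abort_invalid("err_dynamic must be >= 0")
  round_half_up(100 * (err_traditional - err_dynamic) / err_traditional, 0)
}

#' Serialise a fit result to a structured report
#'
#' Writes the parameter table, per-target RMSE, convergence information and
#' the iteration trace to YAML or JSON (chosen by extension).
#'
#' @param fit A `duck_fit` from [fit_lm()] or [fit_gd()].
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  report <- list(
    method = fit$method,
    converged = fit$converged,
    iterations = fit$iterations,
    final_control = as.list(fit$final_control),
    estimates = as.list(fit$estimates),
    rmse = as.list(fit$rmse),
    parameters = lapply(
      unclass(fit$parameters)[setdiff(names(fit$parameters),
                                      c("sf_table", "gamma_table"))],
      identity),
    sf_table = as.list(fit$parameters$sf_table),
    gamma_table = fit$parameters$gamma_table,
    trace = fit$trace)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  } else {
    report$trace <- as.list(report$trace)
    report$gamma_table <- as.list(report$gamma_table)
    yaml::write_yaml(report, path)
  }
  invisible(path)
}
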