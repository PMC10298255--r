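#' An observed (or synthetic) drying curve for one condition
#'
#' @param condition A [drying_conditions()] object.
#' @param times_min Sampling times in minutes, strictly increasing, starting
#'   at 0.
#' @param M_avg Average dry-basis moisture at each time, g/g; the first value
#'   (the initial moisture) must exceed the equilibrium moisture.
#' @param layers Optional matrix of per-layer observations (one row per time,
#'   columns nodes `x = 0..Z`).
#' @param provenance `"weighing"`, `"mri"` or `"synthetic"`.
#' @return An object of class `drying_curve`.
#' @export
drying_curve <- function(condition, times_min, M_avg, layers = NULL,
                         provenance = c("synthetic", "weighing", "mri")) {
  stopifnot(inherits(condition, "drying_conditions"))
  provenance <- match.arg(provenance)
  times_min <- as.numeric(times_min)
  M_avg <- as.numeric(M_avg)
  if (length(times_min) != length(M_avg))
    .stopf("'times_min' and 'M_avg' must have equal length")
  if (times_min[1] != 0 || any(diff(times_min) <= 0))
    .stopf("'times_min' must start at 0 and be strictly increasing")
  if (any(!is.finite(M_avg)) || any(M_avg < 0))
    .stopf("'M_avg' must be finite and non-negative")
  if (M_avg[1] <= condition$equilibrium_moisture)
    .stopf("initial moisture must exceed the equilibrium moisture")
  if (!is.null(layers)) {
    layers <- as.matrix(layers)
    if (nrow(layers) != length(times_min))
      .stopf("'layers' must have one row per sampling time")
  }
  structure(list(condition = condition, times_min = times_min,
                 M_avg = M_avg, layers = layers, provenance = provenance),
            class = "drying_curve")
}

#' @export
print.drying_curve <- function(x, ...) {
  cat(sprintf("Drying curve [%s] %s: %d samples, M %g -> %g g/g\n",
              x$provenance, format(x$condition), length(x$times_min),
              x$M_avg[1], x$M_avg[length(x$M_avg)]))
  invisible(x)
}

#' Root mean square error between predicted and observed moisture
#'
#' `sqrt(sum((pred - obs)^2) / n)` with `n` the number of points.
#'
#' @param predicted,observed Numeric vectors of equal, nonzero length.
#' @return RMSE in the units of the inputs (g/g for moisture curves).
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) == 0L)
    .stopf("'predicted' and 'observed' must have equal nonzero length")
  sqrt(sum((predicted - observed)^2) / length(predicted))
}

#' Determination coefficient between predicted and observed moisture
#'
#' By default computed exactly as the drying-model literature often prints
#' it, with the denominator centered on the mean of the *predicted* values:
#' `1 - sum((pred - obs)^2) / sum((mean(pred) - obs)^2)`. The conventional
#' form centred on the observed mean is available with `mean = "observed"`.
#'
#' @inheritParams rmse
#' @param mean Which mean centres the denominator.
#' @return Dimensionless R^2 (1 for a perfect fit).
#' @export
r_squared <- function(predicted, observed, mean = c("predicted", "observed")) {
  mean <- match.arg(mean)
  if (length(predicted) != length(observed) || length(predicted) < 2L)
    .stopf("need at least two aligned points")
  centre <- if (mean == "predicted") base::mean(predicted) else base::mean(observed)
  den <- sum((centre - observed)^2)
  if (den == 0) .stopf("zero denominator: observations equal the centring mean")
  1 - sum((predicted - observed)^2) / den
}

#' Configuration for least-squares diffusivity fitting
#'
#' @param D0_bounds,Ea_bounds,a_bounds,b_bounds Box bounds for the four
#'   diffusivity-law parameters (`D0` is searched on a log10 scale).
#' @param n_starts Number of Latin-hypercube multi-start points.
#' @param seed Seed for the Latin-hypercube design (fit is deterministic
#'   given the seed).
#' @param maxit Iteration cap per local optimization.
#' @param joint Fit one parameter set jointly across all curves (default) or
#'   one per condition.
#' @param geometry,boundary_scheme,safety Solver options passed to
#'   [simulate_drying()].
#' @param r2_mean Passed to [r_squared()].
#' @param deff_form Algebraic form of the diffusivity law, see [deff_params()].
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(D0_bounds = c(1e-12, 1e-2), Ea_bounds = c(0, 1e5),
                       a_bounds = c(0, 5), b_bounds = c(0, 2),
                       n_starts = 8, seed = 20230605, maxit = 500,
                       joint = TRUE, geometry = "planar",
                       boundary_scheme = "coef6", safety = 0.9,
                       r2_mean = "predicted",
                       deff_form = "exponent") {
  stopifnot(D0_bounds[1] > 0, D0_bounds[2] > D0_bounds[1],
            Ea_bounds[2] >= Ea_bounds[1], a_bounds[2] >= a_bounds[1],
            b_bounds[2] >= b_bounds[1], n_starts >= 1, maxit >= 1)
  structure(list(D0_bounds = D0_bounds, Ea_bounds = Ea_bounds,
                 a_bounds = a_bounds, b_bounds = b_bounds,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 maxit = as.integer(maxit), joint = isTRUE(joint),
                 geometry = geometry, boundary_scheme = boundary_scheme,
                 safety = safety, r2_mean = r2_mean, deff_form = deff_form),
            class = "fit_config")
}

# Predicted average-moisture curve for one observed curve under `params`.
# The t = 0 prediction is the initial moisture itself: the sample is weighed
# before the air-side surface equilibrates. The tiny early-stop tolerance
# keeps the march step count bounded for the large trial diffusivities the
# optimizer visits (past it the film sits at equilibrium anyway); its effect
# on predictions is < 1e-6 of the drying range.
.predict_curve <- function(params, curve, grid, config) {
  tt <- curve$times_min * 60
  sim <- simulate_drying(curve$M_avg[1], params, curve$condition, grid,
                         t_end = max(tt), output_times = tt,
                         geometry = config$geometry,
                         boundary_scheme = config$boundary_scheme,
                         safety = config$safety, stop_tol = 1e-6)
  pred <- sim$M_avg
  pred[tt == 0] <- curve$M_avg[1]
  list(M_pred = pred, history = sim)
}

# Precompute per-curve constants once so the optimizer's objective can call
# the C++ march directly (the march itself costs microseconds; R-level
# object construction would dominate otherwise).
.fit_problem <- function(curves, grid, config) {
  w <- c(0.5, rep(1, grid$Z - 1L), 0.5) / grid$Z  # trapezoid weights
  list(grid = grid, coef = .scheme_coef(config$boundary_scheme),
       geom = .geom_exponent(config$geometry), safety = config$safety,
       w = w,
       curves = lapply(curves, function(cv) {
         tt <- cv$times_min * 60
         list(tt = tt, obs = cv$M_avg, M0 = cv$M_avg[1],
              Me = cv$condition$equilibrium_moisture,
              Tk = cv$condition$temperature_k,
              init = c(rep(cv$M_avg[1], grid$Z),
                       cv$condition$equilibrium_moisture))
       }))
}

.problem_predict <- function(prob, cu, D0, Ea, a, b, form, dfloor) {
  res <- .march_cpp(cu$init, prob$grid$dl, cu$Tk, cu$Me,
                    D0, Ea, a, b, form = form, dfloor = dfloor,
                    geom = prob$geom, bcoef = prob$coef,
                    safety = prob$safety, stop_tol = 1e-6, M0ref = cu$M0,
                    out_times = cu$tt, dt_fixed = -1, max_steps = 1e6)
  if (!res$ok) return(NULL)
  pred <- drop(res$snapshots %*% prob$w)
  pred[cu$tt == 0] <- cu$M0
  pred
}

.pooled_ssr_fast <- function(prob, D0, Ea, a, b, form = 0L, dfloor = 1e-14) {
  ssr <- 0
  for (cu in prob$curves) {
    pred <- .problem_predict(prob, cu, D0, Ea, a, b, form, dfloor)
    if (is.null(pred) || any(!is.finite(pred))) return(1e12)
    ssr <- ssr + sum((pred - cu$obs)^2)
  }
  ssr
}

.pooled_ssr <- function(params, curves, grid, config) {
  prob <- .fit_problem(curves, grid, config)
  .pooled_ssr_fast(prob, params$D0, params$Ea, params$a, params$b,
                   form = if (params$form == "exponent") 0L else 1L,
                   dfloor = params$floor)
}

.params_from_unit <- function(u, config) {
  lo <- log10(config$D0_bounds[1]); hi <- log10(config$D0_bounds[2])
  deff_params(D0 = 10^(lo + u[1] * (hi - lo)),
              Ea = config$Ea_bounds[1] + u[2] * diff(config$Ea_bounds),
              a = config$a_bounds[1] + u[3] * diff(config$a_bounds),
              b = config$b_bounds[1] + u[4] * diff(config$b_bounds),
              form = config$deff_form)
}

.unit_clamp <- function(u) pmin(pmax(u, 0), 1)

# Deterministic warm start: lump the curves' first-mode log-slope into a
# starting D0 guess (initialization only; least squares does the estimating).
.warm_start <- function(curves, grid, config) {
  slopes <- vapply(curves, function(cv) {
    Me <- cv$condition$equilibrium_moisture
    mr <- pmax((cv$M_avg - Me) / (cv$M_avg[1] - Me), 1e-6)
    keep <- which(mr > 0.01)
    if (length(keep) < 2L) return(NA_real_)
    -stats::coef(stats::lm(log(mr[keep]) ~ I(cv$times_min[keep] * 60)))[[2]]
  }, numeric(1))
  Tm <- mean(vapply(curves, function(cv) cv$condition$temperature_k, numeric(1)))
  slope <- mean(slopes, na.rm = TRUE)
  Dhat <- max(slope, 1e-12) * 4 * grid$L^2 / pi^2
  Ea0 <- 2e4
  D0 <- min(max(Dhat / exp(-Ea0 / (.R_GAS * Tm)), config$D0_bounds[1]),
            config$D0_bounds[2])
  lo <- log10(config$D0_bounds[1]); hi <- log10(config$D0_bounds[2])
  .unit_clamp(c((log10(D0) - lo) / (hi - lo),
                (Ea0 - config$Ea_bounds[1]) / max(diff(config$Ea_bounds), 1),
                0.02, 0.02))
}

.fit_variable_one <- function(curves, grid, config) {
  prob <- .fit_problem(curves, grid, config)
  form <- if (config$deff_form == "exponent") 0L else 1L
  obj <- function(u) {
    p <- .params_from_unit(.unit_clamp(u), config)
    .pooled_ssr_fast(prob, p$D0, p$Ea, p$a, p$b, form = form)
  }
  set.seed(config$seed)
  starts <- lhs::randomLHS(config$n_starts, 4)
  starts <- rbind(starts, .warm_start(curves, grid, config))
  best <- NULL
  iters <- 0L
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[k, ], obj, method = "L-BFGS-B", lower = 0, upper = 1,
            control = list(maxit = config$maxit, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    iters <- iters + fit$counts[["function"]]
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) .stopf("all optimizer starts failed")
  # derivative-free polish of the winning start: the adaptive-step solver
  # leaves small kinks in the objective that defeat finite-difference
  # gradients near the optimum
  for (rep in 1:2) {
    polish <- tryCatch(
      optim(best$par, function(u) obj(.unit_clamp(u)),
            method = "Nelder-Mead",
            control = list(maxit = 4L * config$maxit, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value) {
      iters <- iters + polish$counts[["function"]]
      best <- polish
      best$par <- .unit_clamp(best$par)
    }
  }
  list(params = .params_from_unit(.unit_clamp(best$par), config),
       ssr = best$value, converged = best$convergence == 0L,
       iterations = iters, n_starts = nrow(starts))
}

.per_condition_table <- function(curves, preds, config) {
  do.call(rbind, lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    data.frame(condition = format(cv$condition),
               temperature_c = cv$condition$temperature_c,
               relative_humidity = cv$condition$relative_humidity,
               R2 = r_squared(preds[[i]], cv$M_avg, mean = config$r2_mean),
               RMSE = rmse(preds[[i]], cv$M_avg))
  }))
}

.fit_result <- function(model, curves, grid, config, preds, extra) {
  structure(c(list(model = model, curves = curves, grid = grid,
                   config = config,
                   predicted = lapply(seq_along(curves), function(i) {
                     data.frame(time_min = curves[[i]]$times_min,
                                M_pred = preds[[i]])
                   }),
                   per_condition = .per_condition_table(curves, preds, config)),
              extra),
            class = "fit_result")
}

#' Fit the variable-diffusivity drying model to observed curves
#'
#' Minimizes the pooled sum of squared residuals between simulated and
#' observed average moisture over all curves, searching the four
#' diffusivity-law parameters (`D0` on a log scale) inside box bounds with
#' a Latin-hypercube multi-start of bounded quasi-Newton local fits. The
#' fit is deterministic given the configuration seed.
#'
#' @param curves A list of [drying_curve()] objects (each with >= 4 points).
#' @param grid A [shell_grid()].
#' @param config A [fit_config()].
#' @return An object of class `fit_result`: fitted `params` (a
#'   [deff_params()], or a list of them when `config$joint` is `FALSE`),
#'   `per_condition` goodness-of-fit table (R^2, RMSE), `predicted` curves
#'   aligned to the observation times, and `diagnostics` (pooled SSR,
#'   iteration count, convergence flag, seed).
#' @export
fit_variable <- function(curves, grid, config = fit_config()) {
  stopifnot(inherits(grid, "shell_grid"), inherits(config, "fit_config"))
  if (length(curves) < 1L) .stopf("need at least one drying curve")
  for (cv in curves) {
    stopifnot(inherits(cv, "drying_curve"))
    if (length(cv$times_min) < 4L)
      .stopf("each curve needs at least 4 time points")
  }
  if (config$joint) {
    sol <- .fit_variable_one(curves, grid, config)
    preds <- lapply(curves, function(cv)
      .predict_curve(sol$params, cv, grid, config)$M_pred)
    .fit_result("variable", curves, grid, config, preds,
                list(params = sol$params,
                     diagnostics = list(ssr = sol$ssr,
                                        converged = sol$converged,
                                        iterations = sol$iterations,
                                        n_starts = sol$n_starts,
                                        seed = config$seed)))
  } else {
    sols <- lapply(curves, function(cv)
      .fit_variable_one(list(cv), grid, config))
    preds <- lapply(seq_along(curves), function(i)
      .predict_curve(sols[[i]]$params, curves[[i]], grid, config)$M_pred)
    .fit_result("variable", curves, grid, config, preds,
                list(params = lapply(sols, `[[`, "params"),
                     diagnostics = list(
                       ssr = sum(vapply(sols, `[[`, numeric(1), "ssr")),
                       converged = all(vapply(sols, `[[`, logical(1),
                                              "converged")),
                       iterations = sum(vapply(sols, `[[`, integer(1),
                                               "iterations")),
                       n_starts = sols[[1]]$n_starts,
                       seed = config$seed)))
  }
}

#' Fit the constant-diffusivity benchmark model
#'
#' One scalar diffusivity per condition, found by golden-section search on
#' a log10 scale against the same residuals as [fit_variable()].
#'
#' @inheritParams fit_variable
#' @return A `fit_result` whose `D` field is a named per-condition vector of
#'   fitted diffusivities (m^2 s^-1).
#' @export
fit_constant <- function(curves, grid, config = fit_config()) {
  stopifnot(inherits(grid, "shell_grid"), inherits(config, "fit_config"))
  if (length(curves) < 1L) .stopf("need at least one drying curve")
  for (cv in curves) {
    stopifnot(inherits(cv, "drying_curve"))
    if (length(cv$times_min) < 4L)
      .stopf("each curve needs at least 4 time points")
  }
  lo <- log10(config$D0_bounds[1]); hi <- log10(config$D0_bounds[2])
  Ds <- vapply(curves, function(cv) {
    prob <- .fit_problem(list(cv), grid, config)
    f <- function(ld) .pooled_ssr_fast(prob, 10^ld, 0, 0, 0)
    # the SSR is flat on both wings (no drying / instant drying), so a
    # coarse log-grid scan brackets the interior minimum before the
    # golden-section refinement
    ld_grid <- seq(lo, hi, length.out = 41L)
    vals <- vapply(ld_grid, f, numeric(1))
    k <- which.min(vals)
    span <- c(ld_grid[max(1L, k - 1L)], ld_grid[min(length(ld_grid), k + 1L)])
    10^optimize(f, span, tol = 1e-7)$minimum
  }, numeric(1))
  names(Ds) <- vapply(curves, function(cv) format(cv$condition), character(1))
  preds <- lapply(seq_along(curves), function(i)
    .predict_curve(deff_params(D0 = Ds[i]), curves[[i]], grid,
                   config)$M_pred)
  ssr <- sum(vapply(seq_along(curves), function(i)
    sum((preds[[i]] - curves[[i]]$M_avg)^2), numeric(1)))
  .fit_result("constant", curves, grid, config, preds,
              list(D = Ds,
                   diagnostics = list(ssr = ssr, converged = TRUE,
                                      iterations = NA_integer_,
                                      n_starts = 1L, seed = config$seed)))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s-diffusivity fit over %d condition(s); pooled SSR = %.4g\n",
              x$model, length(x$curves), x$diagnostics$ssr))
  print(x$per_condition, row.names = FALSE)
  invisible(x)
}

#' Compare the variable- and constant-diffusivity fits
#'
#' @param fit_v,fit_c `fit_result` objects from [fit_variable()] and
#'   [fit_constant()] on identical observations.
#' @return A list of class `model_comparison` with `summary` (per-condition
#'   R^2/RMSE of both models and their deltas) and `per_time` (per-time
#'   relative errors of each model, percent).
#' @export
compare_models <- function(fit_v, fit_c) {
  stopifnot(inherits(fit_v, "fit_result"), inherits(fit_c, "fit_result"))
  if (length(fit_v$curves) != length(fit_c$curves))
    .stopf("fits cover different numbers of conditions")
  for (i in seq_along(fit_v$curves)) {
    if (!isTRUE(all.equal(fit_v$curves[[i]]$M_avg, fit_c$curves[[i]]$M_avg)))
      .stopf("fits were not computed on identical observations")
  }
  sv <- fit_v$per_condition; sc <- fit_c$per_condition
  summary <- data.frame(condition = sv$condition,
                        temperature_c = sv$temperature_c,
                        relative_humidity = sv$relative_humidity,
                        R2_variable = sv$R2, R2_constant = sc$R2,
                        RMSE_variable = sv$RMSE, RMSE_constant = sc$RMSE,
                        dR2 = sv$R2 - sc$R2, dRMSE = sv$RMSE - sc$RMSE)
  per_time <- do.call(rbind, lapply(seq_along(fit_v$curves), function(i) {
    cv <- fit_v$curves[[i]]
    data.frame(condition = format(cv$condition),
               time_min = cv$times_min,
               M_obs = cv$M_avg,
               M_pred_variable = fit_v$predicted[[i]]$M_pred,
               M_pred_constant = fit_c$predicted[[i]]$M_pred,
               rel_err_variable = 100 * abs(fit_v$predicted[[i]]$M_pred -
                                              cv$M_avg) / cv$M_avg,
               rel_err_constant = 100 * abs(fit_c$predicted[[i]]$M_pred -
                                              cv$M_avg) / cv$M_avg)
  }))
  structure(list(summary = summary, per_time = per_time),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Variable- vs constant-diffusivity model comparison\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
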