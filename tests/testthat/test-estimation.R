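test_that("rmse matches hand-computed values and validates input", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(2, 1), 1)
  expect_equal(rmse(c(1, 2, 3), c(1, 1, 1)), sqrt(5 / 3))
  expect_error(rmse(1:3, 1:2), "equal")
  expect_error(rmse(numeric(0), numeric(0)), "nonzero")
})

test_that("R^2 uses the predicted-mean denominator and is permutation-invariant", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  # hand value: num = 1, den = sum((2 - obs)^2) = 5 with obs = (1, 2, 4)
  pred <- c(1, 2, 3); obs <- c(1, 2, 4)
  expect_equal(r_squared(pred, obs), 1 - 1 / 5)
  idx <- c(3, 1, 2)
  expect_equal(r_squared(pred[idx], obs[idx]), r_squared(pred, obs))
  # conventional observed-mean form differs when means differ
  expect_equal(r_squared(pred, obs, mean = "observed"),
               1 - 1 / sum((obs - mean(obs))^2))
  expect_error(r_squared(c(2, 2, 2), c(2, 2, 2)), "denominator")
  expect_error(r_squared(1, 1), "two")
})

test_that("drying curves enforce their invariants", {
  cond <- drying_conditions(35, 60, 0.1)
  expect_error(drying_curve(cond, c(10, 20), c(5, 4)), "start at 0")
  expect_error(drying_curve(cond, c(0, 20, 20), c(5, 4, 3)), "increasing")
  expect_error(drying_curve(cond, c(0, 20), c(0.05, 0.04)), "exceed")
  cv <- drying_curve(cond, c(0, 20, 40), c(8, 5, 3))
  expect_s3_class(cv, "drying_curve")
})

test_that("constant-diffusivity fit recovers known truth on noiseless data", {
  D_true <- 5e-12
  cv <- constant_d_curve(D = D_true)
  fit <- fit_constant(list(cv), shell_grid(2e-4, 4))
  expect_equal(unname(fit$D[1]), D_true, tolerance = 1e-4)
  expect_gt(fit$per_condition$R2[1], 0.9999)
  expect_lt(fit$per_condition$RMSE[1], 1e-3)
})

test_that("variable fit restricted to a = b = 0 recovers the lumped diffusivity", {
  # a single temperature cannot separate D0 from Ea, but the lumped
  # D0*exp(-Ea/RT) is identified
  D_true <- 5e-12
  cv <- constant_d_curve(D = D_true)
  cfgf <- fit_config(a_bounds = c(0, 0), b_bounds = c(0, 0),
                     n_starts = 4, maxit = 200)
  fit <- fit_variable(list(cv), shell_grid(2e-4, 4), cfgf)
  lumped <- constant_diffusivity(fit$params, cv$condition$temperature_k)
  expect_lt(abs(lumped / D_true - 1), 0.1)
})

test_that("fit preconditions are enforced", {
  cond <- drying_conditions(35, 60, 0.1)
  short <- drying_curve(cond, c(0, 20, 40), c(8, 5, 3))
  g <- shell_grid(2e-4, 4)
  expect_error(fit_variable(list(short), g), "at least 4")
  expect_error(fit_variable(list(), g), "at least one")
  expect_error(fit_constant(list(), g), "at least one")
  expect_error(fit_constant(list(short), g), "at least 4")
})

test_that("model comparison reports zero deltas for identical fits and full tables", {
  cv <- constant_d_curve()
  g <- shell_grid(2e-4, 4)
  fit <- fit_constant(list(cv), g)
  cmp <- compare_models(fit, fit)
  expect_equal(cmp$summary$dR2, 0)
  expect_equal(cmp$summary$dRMSE, 0)
  expect_equal(nrow(cmp$summary), 1L)
  expect_equal(nrow(cmp$per_time), length(cv$times_min))
  # mismatched observations are refused
  cv2 <- constant_d_curve(D = 8e-12)
  fit2 <- fit_constant(list(cv2), g)
  expect_error(compare_models(fit, fit2), "identical")
})

test_that("variable model dominates the constant model at the optimum", {
  # nested-model dominance on the default noisy fixture
  fv <- default_variable_fit()
  fc <- default_constant_fit()
  expect_lte(fv$diagnostics$ssr, fc$diagnostics$ssr)
  cmp <- compare_models(fv, fc)
  expect_equal(nrow(cmp$summary), 5L)
  expect_true(all(cmp$summary$RMSE_variable <= cmp$summary$RMSE_constant))
})

test_that("noiseless synthetic curves are reproduced almost exactly by the refit", {
  cfg <- generator_config(noise_cv = 0, conditions = default_conditions()[3:5])
  curves <- generate_drying_experiment(cfg)
  fit <- fit_variable(curves, cfg$grid, fit_config(n_starts = 4))
  expect_true(all(fit$per_condition$R2 > 0.999))
})

test_that("diffusivity recovery is robust to 5% noise across seeded replicates", {
  # 3 temperatures x 7 time points, 5% multiplicative noise; the refitted
  # diffusivity surface stays within 25% of truth in >= 90% of replicates
  # over the moisture range the samples actually traverse (the film falls
  # from 8.44 to ~5 g/g inside the first sampling interval, so the law
  # above ~5 g/g is unconstrained extrapolation)
  truep <- default_true_params()
  conds <- default_conditions()[3:5]
  grid <- shell_grid(2e-4, 4)
  Mg <- c(0.5, 1, 2, 4)
  cheap <- fit_config(n_starts = 4, maxit = 300)
  ok <- vapply(1:20, function(s) {
    cfg <- generator_config(conditions = conds, sampling_interval = 20,
                            duration = 120, seed = 1000 + s)
    curves <- generate_drying_experiment(cfg)
    fit <- fit_variable(curves, grid, cheap)
    rel <- vapply(c(308.15, 313.15, 318.15), function(Tk) {
      max(abs(effective_diffusivity(fit$params, Mg, Tk) /
                effective_diffusivity(truep, Mg, Tk) - 1))
    }, numeric(1))
    max(rel) < 0.25
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
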