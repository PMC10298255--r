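cond35 <- drying_conditions(35, 60, 0.1)

test_that("shell grid divides the thickness exactly", {
  g <- shell_grid(0.0002, 4)
  expect_equal(g$dl, 5e-5)
  expect_length(g$x, 5L)
  expect_equal(g$dl * g$Z, g$L)
  g2 <- shell_grid(1, 2)
  expect_equal(g2$dl, 0.5)
  expect_length(g2$x, 3L)
  expect_equal(shell_grid(0.0002, 64)$dl, 3.125e-6)
  expect_error(shell_grid(0, 4), "positive")
  expect_error(shell_grid(0.0002, 1), ">= 2")
})

test_that("stable timestep honours the stricter inner-node bound and scales as dl^2", {
  g <- shell_grid(2e-4, 4)  # dl = 5e-5
  expect_equal(stable_timestep(g, 5e-10, safety = 1), 2.5e-9 / 3e-9)
  expect_equal(stable_timestep(g, 5e-10, safety = 0.9),
               0.9 * stable_timestep(g, 5e-10, safety = 1))
  g2 <- shell_grid(2e-4, 8)  # halved dl
  expect_equal(stable_timestep(g2, 5e-10, safety = 1),
               stable_timestep(g, 5e-10, safety = 1) / 4)
  expect_error(stable_timestep(g, 0), "positive")
  expect_error(stable_timestep(g, 5e-10, safety = 1.2), "safety")
})

test_that("a field at equilibrium is a fixed point of the step", {
  g <- shell_grid(2e-4, 4)
  f <- moisture_field(g, rep(0.1, 5))
  p <- deff_params(D0 = 5e-12)
  dt <- stable_timestep(g, 5e-12)
  for (i in 1:20) f <- step_variable(f, p, cond35, dt)
  expect_equal(f$values, rep(0.1, 5))
})

test_that("one explicit step dries every interior node and respects stability", {
  g <- shell_grid(2e-4, 4)
  f <- moisture_field(g, c(rep(8.44, 4), 0.1))
  p <- deff_params(D0 = 5e-12)
  dt <- stable_timestep(g, 5e-12)
  f1 <- step_variable(f, p, cond35, dt)
  expect_true(all(f1$values <= f$values))
  expect_true(f1$values[4] < f$values[4])  # node next to the surface dries
  expect_equal(f1$values[5], 0.1)          # surface stays pinned
  # refusal to step beyond the stability bound
  expect_error(step_variable(f, p, cond35, dt * 2), "stability")
})

test_that("uniform diffusivity collapses the variable step onto the constant step", {
  g <- shell_grid(2e-4, 4)
  f <- moisture_field(g, c(8.44, 7.1, 4.2, 1.5, 0.1))
  p0 <- deff_params(D0 = 5e-12)
  dt <- stable_timestep(g, 5e-12)
  expect_equal(step_variable(f, p0, cond35, dt)$values,
               step_constant(f, 5e-12, cond35, dt)$values)
  # uniform moisture makes the moisture-dependent law spatially uniform too
  fu <- moisture_field(g, rep(3, 5))
  pv <- deff_params(D0 = 5e-12, a = 0.2, b = 0.05)
  Du <- effective_diffusivity(pv, 3, cond35$temperature_k)
  dtu <- stable_timestep(g, Du)
  expect_equal(step_variable(fu, pv, cond35, dtu)$values,
               step_constant(fu, Du, cond35, dtu)$values)
})

test_that("halving the step converges at second order over one interval", {
  g <- shell_grid(2e-4, 8)
  # smooth profile compatible with both boundaries (zero-flux inner,
  # pinned outer), so the one-interval error is cleanly O(dt^2)
  prof <- 0.1 + 8.34 * cos(pi * g$x / (2 * g$L))
  f0 <- moisture_field(g, prof)
  D <- 5e-12
  dt <- 0.5 * stable_timestep(g, D, safety = 1)
  advance <- function(f, dt, n) {
    for (i in seq_len(n)) f <- step_constant(f, D, cond35, dt)
    f$values
  }
  d1 <- max(abs(advance(f0, dt, 1) - advance(f0, dt / 2, 2)))
  d2 <- max(abs(advance(f0, dt / 2, 2) - advance(f0, dt / 4, 4)))
  expect_gt(d1 / d2, 2.5)  # ~4 for an O(dt^2) one-interval error
})

test_that("perturbation amplitude decays monotonically", {
  g <- shell_grid(2e-4, 8)
  bump <- 0.1 + 2 * exp(-((0:8) - 4)^2 / 4)
  f <- moisture_field(g, c(bump[-9], 0.1))
  D <- 5e-12
  dt <- stable_timestep(g, D)
  amp <- numeric(50)
  for (i in 1:50) {
    f <- step_constant(f, D, cond35, dt)
    amp[i] <- max(f$values - 0.1)
  }
  expect_true(all(diff(amp) <= 0))
})

test_that("analytic slab series has the right endpoints and decay", {
  expect_equal(analytic_slab_ratio(5e-10, 2e-4, 0, n_terms = 5000), 1,
               tolerance = 1e-3)
  # frozen from an arbitrary-precision summation (50 terms)
  expect_equal(analytic_slab_ratio(5e-10, 2e-4, 40, n_terms = 50),
               0.23604966925615119, tolerance = 1e-12)
  # large-time limit: first term dominates
  D <- 5e-10; L <- 2e-4; t <- 150
  expect_equal(analytic_slab_ratio(D, L, t),
               8 / pi^2 * exp(-pi^2 * D * t / (4 * L^2)), tolerance = 1e-6)
  expect_error(analytic_slab_ratio(5e-10, 2e-4, 40, n_terms = 0), "n_terms")
})

test_that("simulated drying matches the reference single-step implementation", {
  # fixed-step C++ march against the R stepping functions, exact agreement
  g <- shell_grid(2e-4, 4)
  p <- deff_params(D0 = 1.2e-7, Ea = 2.5e4, a = 0.04, b = 0.025)
  Dmax <- effective_diffusivity(p, 8.44, cond35$temperature_k)
  dt <- 10
  n <- 24L
  hist <- simulate_drying(8.44, p, cond35, g, t_end = n * dt,
                          output_times = c(0, n * dt), stop_tol = 0, dt = dt)
  f <- moisture_field(g, c(rep(8.44, 4), 0.1))
  for (i in seq_len(n)) f <- step_variable(f, p, cond35, dt)
  expect_equal(unname(hist$fields[2, ]), f$values, tolerance = 1e-12)
})

test_that("constant-diffusivity march agrees with the analytic series oracle", {
  g <- shell_grid(2e-4, 64)
  D <- 5e-10
  tt <- seq(5, 150, by = 5)
  hist <- simulate_drying(1, deff_params(D0 = D),
                          drying_conditions(35, 60, 0), g,
                          t_end = 150, output_times = tt,
                          boundary_scheme = "ghost", stop_tol = 0)
  exact <- analytic_slab_ratio(D, g$L, tt, n_terms = 200)
  expect_lt(max(abs(hist$M_avg - exact)), 1e-3)
})

test_that("coefficient-6 and ghost boundary schemes converge together under refinement", {
  # the coefficient-6 inner-node update is first-order at the sealed face:
  # the gap to the ghost-node scheme halves with each grid doubling and is
  # below 1e-3 on a Z = 256 grid
  D <- 5e-10
  cond <- drying_conditions(35, 60, 0)
  gap <- vapply(c(64L, 128L, 256L), function(Z) {
    g <- shell_grid(2e-4, Z)
    tt <- seq(5, 150, by = 10)
    mp <- simulate_drying(1, deff_params(D0 = D), cond, g, 150, tt,
                          boundary_scheme = "coef6", stop_tol = 0)$M_avg
    mg <- simulate_drying(1, deff_params(D0 = D), cond, g, 150, tt,
                          boundary_scheme = "ghost", stop_tol = 0)$M_avg
    max(abs(mp - mg))
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
  expect_gt(gap[1] / gap[2], 1.5)
  expect_lt(gap[3], 1e-3)
})

test_that("grid refinement changes the averaged curve by a shrinking amount", {
  p <- deff_params(D0 = 1.2e-7, Ea = 2.5e4, a = 0.04, b = 0.025)
  tt <- seq(0, 140, 20) * 60
  runZ <- function(Z) simulate_drying(8.44, p, cond35, shell_grid(2e-4, Z),
                                      max(tt), tt, stop_tol = 0)$M_avg
  m4 <- runZ(4); m8 <- runZ(8); m16 <- runZ(16)
  d1 <- max(abs(m8 - m4)); d2 <- max(abs(m16 - m8))
  expect_gt(d1 / d2, 1.8)  # empirical order >= 1 in dl
})

test_that("long simulations settle at the equilibrium moisture", {
  p <- deff_params(D0 = 1.2e-7, Ea = 2.5e4, a = 0.04, b = 0.025)
  g <- shell_grid(2e-4, 4)
  hist <- simulate_drying(8.44, p, cond35, g, t_end = 1e6,
                          output_times = c(0, 1e6))
  expect_lt(max(abs(hist$fields[2, ] - 0.1)), 0.02)
  expect_true(hist$scheme$early_stop)
  # degenerate start at equilibrium: flat history
  flat <- simulate_drying(0.1, p, cond35, g, 100, c(0, 50, 100))
  expect_true(all(flat$fields == 0.1))
})

test_that("average moisture is the trapezoid mean", {
  g <- shell_grid(2e-4, 4)
  expect_equal(average_moisture(moisture_field(g, rep(3, 5))), 3)
  lin <- seq(0.1, 8.44, length.out = 5)
  expect_equal(average_moisture(moisture_field(g, lin)), (0.1 + 8.44) / 2)
  prof <- c(2, 1.5, 1.2, 0.8, 0.3)
  expect_equal(average_moisture(moisture_field(g, prof)), 4.65 / 4)
})

test_that("moisture-weighted average diffusivity matches hand values", {
  g <- shell_grid(2e-4, 2)
  p <- deff_params(D0 = 1e-9, a = 0.1)
  # frozen from an arbitrary-precision evaluation of sum(D(M)*M)/sum(M)
  expect_equal(deff_avg(moisture_field(g, c(1, 2, 3)), p, 308.15),
               1.2662588095206661e-9, tolerance = 1e-14)
  # uniform moisture: weights cancel
  expect_equal(deff_avg(moisture_field(g, rep(2, 3)), p, 308.15),
               effective_diffusivity(p, 2, 308.15))
  # a = b = 0: field-independent
  p0 <- deff_params(D0 = 4e-12, Ea = 3e4)
  expect_equal(deff_avg(moisture_field(g, c(0.5, 3, 8)), p0, 313.15),
               constant_diffusivity(p0, 313.15))
  expect_error(deff_avg(rep(0, 3), p, 308.15), "undefined")
})

test_that("maximum principle and monotone drying hold across random parameter draws", {
  # randomized draws across the physically plausible parameter box
  set.seed(42)
  g <- shell_grid(2e-4, 4)
  for (i in 1:10) {
    p <- deff_params(D0 = 10^runif(1, -8, -6), Ea = runif(1, 1e4, 4e4),
                     a = runif(1, 0, 0.3), b = runif(1, 0, 0.1))
    Tc <- sample(c(35, 40, 45), 1)
    Me <- runif(1, 0.02, 0.3)
    M0 <- runif(1, 2, 10)
    cond <- drying_conditions(Tc, 60, Me)
    hist <- simulate_drying(M0, p, cond, g, t_end = 140 * 60,
                            output_times = seq(0, 140, 10) * 60,
                            stop_tol = 0)
    expect_true(all(hist$fields >= Me - 1e-12))
    expect_true(all(hist$fields <= M0 + 1e-12))
    expect_true(all(diff(hist$M_avg) <= 1e-12))
  }
})
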