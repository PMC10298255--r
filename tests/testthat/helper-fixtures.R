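# Shared fixtures, lazily computed and cached across test files (the joint
# variable-diffusivity fit is the expensive piece; everything else is cheap).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# The default five-condition synthetic experiment (study conditions:
# M0 = 8.44 g/g, 20-min sampling over 140 min, noise CV 0.05, seed 20230605)
default_experiment <- function() {
  fixture("default_experiment", function() {
    generate_drying_experiment(generator_config())
  })
}

# Joint variable-diffusivity refit of the default experiment
default_variable_fit <- function() {
  fixture("default_variable_fit", function() {
    cfg <- attr(default_experiment(), "config")
    fit_variable(default_experiment(), cfg$grid)
  })
}

default_constant_fit <- function() {
  fixture("default_constant_fit", function() {
    cfg <- attr(default_experiment(), "config")
    fit_constant(default_experiment(), cfg$grid)
  })
}

# A cheap single-condition noiseless curve from known constant-D truth
constant_d_curve <- function(D = 5e-12, Me = 0.1, M0 = 8.44) {
  cond <- drying_conditions(35, 60, Me)
  grid <- shell_grid(2e-4, 4)
  tt <- seq(0, 140, 20) * 60
  hist <- simulate_drying(M0, deff_params(D0 = D), cond, grid,
                          t_end = max(tt), output_times = tt, stop_tol = 0)
  M <- hist$M_avg
  M[1] <- M0
  drying_curve(cond, tt / 60, M)
}
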