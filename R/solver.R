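#' Spatial grid across the film thickness
#'
#' Divides a film of thickness `L` into `Z` layers of equal spacing
#' `dl = L/Z`, giving `Z + 1` nodes indexed `x = 0..Z`. Node `x = 0` is the
#' inner face sealed against the preparation pin (zero moisture flux) and
#' node `x = Z` is the outer air-side face, held at the equilibrium moisture
#' content from `t = 0+`.
#'
#' @param L Film thickness, m.
#' @param Z Number of layers (integer >= 2).
#' @return An object of class `shell_grid` with fields `L`, `Z`, `dl` and
#'   node positions `x` (m).
#' @examples
#' shell_grid(L = 0.0002, Z = 4)  # the capsule-shell default: dl = 5e-5 m
#' @export
shell_grid <- function(L, Z) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    .stopf("'L' must be a single positive thickness in metres")
  if (!is.numeric(Z) || length(Z) != 1L || Z != as.integer(Z) || Z < 2)
    .stopf("'Z' must be an integer >= 2")
  Z <- as.integer(Z)
  structure(list(L = L, Z = Z, dl = L / Z, x = (0:Z) * (L / Z)),
            class = "shell_grid")
}

#' @export
print.shell_grid <- function(x, ...) {
  cat(sprintf("Shell grid: L = %g m, Z = %d layers, dl = %g m (%d nodes)\n",
              x$L, x$Z, x$dl, x$Z + 1L))
  invisible(x)
}

#' Largest stable explicit time step
#'
#' The explicit scheme is stable only when the time step respects
#' `dt <= dl^2 / (c * D)`. The coefficient-6 inner-node update carries the
#' stricter bound `c = 6` (interior nodes need only `c = 2`),
#' so the step honours `dl^2 / (6 * Dmax)` scaled by a safety fraction.
#'
#' @param grid A [shell_grid()].
#' @param Dmax The largest nodal diffusivity expected during the step,
#'   m^2 s^-1.
#' @param safety Fraction of the bound actually used, in (0, 1].
#' @return Time step in seconds.
#' @export
stable_timestep <- function(grid, Dmax, safety = 0.9) {
  stopifnot(inherits(grid, "shell_grid"))
  if (!is.numeric(Dmax) || length(Dmax) != 1L || !is.finite(Dmax) || Dmax <= 0)
    .stopf("'Dmax' must be a single positive diffusivity")
  if (!is.numeric(safety) || length(safety) != 1L ||
      safety <= 0 || safety > 1)
    .stopf("'safety' must be in (0, 1]")
  safety * grid$dl^2 / (6 * Dmax)
}

#' Moisture values on the grid nodes at one instant
#'
#' @param grid A [shell_grid()].
#' @param values Dry-basis moisture at nodes `x = 0..Z`, g/g; length `Z + 1`,
#'   all finite and non-negative.
#' @param time Time since the start of drying, s.
#' @return An object of class `moisture_field`.
#' @export
moisture_field <- function(grid, values, time = 0) {
  stopifnot(inherits(grid, "shell_grid"))
  if (length(values) != grid$Z + 1L)
    .stopf("'values' must have length Z + 1 = %d", grid$Z + 1L)
  if (any(!is.finite(values)) || any(values < 0))
    .stopf("moisture values must be finite and non-negative")
  structure(list(grid = grid, values = as.numeric(values),
                 time = as.numeric(time)),
            class = "moisture_field")
}

.scheme_coef <- function(boundary_scheme) {
  switch(boundary_scheme, coef6 = 6L, ghost = 2L,
         .stopf("unknown boundary scheme '%s'", boundary_scheme))
}

.geom_exponent <- function(geometry) {
  switch(geometry, planar = 0, cylindrical = 1, spherical = 2,
         .stopf("unknown geometry '%s'", geometry))
}

#' Advance the moisture field one explicit time step (variable diffusivity)
#'
#' Reference single-step implementation of the explicit scheme. The inner
#' sealed node is updated by the relaxation rule
#' `M0 <- M0 + c*D0*dt/dl^2 * (M1 - M0)` with `c = 6` (the form common in
#' the thin-layer drying literature) or `c = 2` (textbook ghost node);
#' interior nodes use the conservative stencil
#' `M <- M + dt * (D * Mxx + dD/dx * dM/dx)` with central differences, the
#' outer node stays pinned at the equilibrium moisture. Nodal diffusivities
#' come from [effective_diffusivity()] at the condition temperature. The
#' step refuses to run if `dt` violates the stability bound for the current
#' maximum nodal diffusivity.
#'
#' @param field A [moisture_field()].
#' @param params A [deff_params()] object.
#' @param cond A [drying_conditions()] object.
#' @param dt Time step, s.
#' @param geometry `"planar"` (default), `"cylindrical"` or `"spherical"`;
#'   the curvilinear options add the `g * D/r * dM/dx` term at interior
#'   nodes with `r = x * dl`.
#' @param boundary_scheme `"coef6"` (inner-node coefficient 6, the default)
#'   or `"ghost"` (textbook ghost-node coefficient 2).
#' @return The updated [moisture_field()] at `time + dt`.
#' @export
step_variable <- function(field, params, cond, dt,
                          geometry = "planar", boundary_scheme = "coef6") {
  stopifnot(inherits(field, "moisture_field"),
            inherits(params, "deff_params"),
            inherits(cond, "drying_conditions"))
  coef <- .scheme_coef(boundary_scheme)
  g <- .geom_exponent(geometry)
  grid <- field$grid
  Z <- grid$Z
  dl <- grid$dl
  M <- field$values
  D <- effective_diffusivity(params, M, cond$temperature_k)
  bound <- dl^2 / (coef * max(D))
  if (dt > bound * (1 + 1e-12))
    .stopf("dt = %g s violates the stability bound %g s for Dmax = %g",
           dt, bound, max(D))
  Mn <- M
  Mn[1] <- M[1] + coef * D[1] * dt / dl^2 * (M[2] - M[1])
  i <- seq(2L, Z)
  lap <- (M[i + 1L] - 2 * M[i] + M[i - 1L]) / dl^2
  gradD <- (D[i + 1L] - D[i - 1L]) / (2 * dl)
  gradM <- (M[i + 1L] - M[i - 1L]) / (2 * dl)
  upd <- D[i] * lap + gradD * gradM
  if (g > 0) upd <- upd + g * D[i] / ((i - 1L) * dl) * gradM
  Mn[i] <- M[i] + dt * upd
  Mn[Z + 1L] <- cond$equilibrium_moisture
  moisture_field(grid, pmax(Mn, 0), field$time + dt)
}

#' Advance the moisture field one explicit step (constant diffusivity)
#'
#' Identical to [step_variable()] with the diffusivity fixed at `D` on all
#' nodes (the gradient-of-D term vanishes).
#'
#' @inheritParams step_variable
#' @param D Constant diffusivity, m^2 s^-1.
#' @export
step_constant <- function(field, D, cond, dt,
                          geometry = "planar", boundary_scheme = "coef6") {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    .stopf("'D' must be a single positive diffusivity")
  step_variable(field, deff_params(D0 = D), cond, dt,
                geometry = geometry, boundary_scheme = boundary_scheme)
}

#' Simulate a full drying run
#'
#' Initializes all nodes at `M0` with the outer node pinned at the
#' equilibrium moisture (the air-side surface equilibrates instantaneously),
#' then marches the explicit scheme with a stability-bounded step recomputed
#' every iteration from the current maximum nodal diffusivity. Snapshots at
#' `output_times` are obtained by linear interpolation between the two
#' bracketing internal steps. The march terminates early once the mean
#' moisture ratio `(M_avg - Me)/(M0 - Me)` drops below `stop_tol`
#' (remaining snapshots repeat the final state), or at `t_end`.
#'
#' @param M0 Initial dry-basis moisture content, g/g; must exceed the
#'   equilibrium moisture of `cond`.
#' @param params A [deff_params()] object.
#' @param cond A [drying_conditions()] object.
#' @param grid A [shell_grid()].
#' @param t_end Hard cap on simulated time, s.
#' @param output_times Times (s) at which snapshots are requested; all must
#'   lie in `[0, t_end]`.
#' @param geometry,boundary_scheme See [step_variable()].
#' @param safety Stability safety fraction in (0, 1].
#' @param stop_tol Early-termination tolerance on the normalized moisture
#'   ratio; `0` disables early stopping.
#' @param dt Optional fixed time step (s) overriding the adaptive one; the
#'   caller is responsible for stability.
#' @return An object of class `moisture_history`: list with `times` (s),
#'   `fields` (matrix, one row per snapshot, columns `x = 0..Z`), `M_avg`
#'   (trapezoid-weighted spatial means), `grid`, `condition`, and `scheme`
#'   metadata (step counts, dt range, scheme flags).
#' @export
simulate_drying <- function(M0, params, cond, grid, t_end, output_times,
                            geometry = "planar", boundary_scheme = "coef6",
                            safety = 0.9, stop_tol = 1e-3, dt = NULL) {
  stopifnot(inherits(params, "deff_params"),
            inherits(cond, "drying_conditions"),
            inherits(grid, "shell_grid"))
  Me <- cond$equilibrium_moisture
  if (!is.numeric(M0) || length(M0) != 1L || !is.finite(M0) || M0 < Me)
    .stopf("'M0' must be at least the equilibrium moisture (%g g/g)", Me)
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0)
    .stopf("'t_end' must be positive")
  output_times <- sort(as.numeric(output_times))
  if (length(output_times) < 1L)
    .stopf("'output_times' must contain at least one time")
  if (any(output_times < 0) || any(output_times > t_end))
    .stopf("'output_times' must lie within [0, t_end]")
  coef <- .scheme_coef(boundary_scheme)
  g <- .geom_exponent(geometry)
  if (safety <= 0 || safety > 1) .stopf("'safety' must be in (0, 1]")

  init <- c(rep(M0, grid$Z), Me)
  res <- .march_cpp(init, grid$dl, cond$temperature_k, Me,
                    params$D0, params$Ea, params$a, params$b,
                    form = if (params$form == "exponent") 0L else 1L,
                    dfloor = params$floor, geom = g, bcoef = coef,
                    safety = safety, stop_tol = stop_tol, M0ref = M0,
                    out_times = output_times,
                    dt_fixed = if (is.null(dt)) -1 else dt,
                    max_steps = 2e7)
  if (!res$ok)
    .stopf("finite-difference march failed (non-finite state or step cap)")
  fields <- res$snapshots
  colnames(fields) <- paste0("M_x", 0:grid$Z)
  structure(list(
    times = output_times,
    fields = fields,
    M_avg = apply(fields, 1L, .trapz_mean),
    grid = grid,
    condition = cond,
    scheme = list(geometry = geometry, boundary_scheme = boundary_scheme,
                  safety = safety, stop_tol = stop_tol,
                  steps = res$steps, dt_min = res$dt_min,
                  dt_max = res$dt_max, early_stop = res$early_stop,
                  t_stop = res$t_stop)),
    class = "moisture_history")
}

#' @export
print.moisture_history <- function(x, ...) {
  cat(sprintf(
    "Moisture history: %d snapshots over %g s (%s, %s scheme, %g steps)\n",
    length(x$times), max(x$times), x$scheme$geometry,
    x$scheme$boundary_scheme, x$scheme$steps))
  cat(sprintf("  condition %s; M_avg %g -> %g g/g\n",
              format(x$condition), x$M_avg[1], x$M_avg[length(x$M_avg)]))
  invisible(x)
}

# trapezoid mean over a uniform node vector
.trapz_mean <- function(v) {
  n <- length(v)
  (0.5 * v[1] + sum(v[seq(2L, n - 1L)]) + 0.5 * v[n]) / (n - 1L)
}

#' Spatial average moisture of a field
#'
#' Trapezoid-weighted mean over the uniformly spaced nodes `x = 0..Z`
#' (end nodes carry half weight).
#'
#' @param field A [moisture_field()] or a numeric node vector.
#' @return Average dry-basis moisture, g/g.
#' @export
average_moisture <- function(field) {
  v <- if (inherits(field, "moisture_field")) field$values else field
  if (length(v) < 3L) .stopf("need at least 3 nodes")
  .trapz_mean(v)
}

#' Moisture-weighted average effective diffusivity
#'
#' Discrete reading of the mean local diffusivity over the film,
#' `sum(D_eff(M_x, T) * M_x) / sum(M_x)`: local diffusivities weighted by the
#' local moisture they act on. Undefined for an all-dry field.
#'
#' @param field A [moisture_field()] or numeric node vector.
#' @param params A [deff_params()] object.
#' @param T_K Film temperature, K.
#' @return Average diffusivity, m^2 s^-1.
#' @export
deff_avg <- function(field, params, T_K) {
  v <- if (inherits(field, "moisture_field")) field$values else field
  if (sum(v) <= 0) .stopf("all-zero moisture field: average undefined")
  D <- effective_diffusivity(params, v, T_K)
  sum(D * v) / sum(v)
}

#' Analytic series solution for drying of a sealed/exposed slab
#'
#' Verification oracle for the constant-diffusivity solver: the classical
#' separation-of-variables solution for a slab of thickness `L`, insulated
#' at `x = 0` and held at the equilibrium moisture at `x = L` (equivalent to
#' the even modes of a `2L` slab). Returns the average moisture ratio
#' \deqn{MR(t) = \sum_{n=0}^{N} \frac{8}{(2n+1)^2 \pi^2}
#'   \exp\!\left(-\frac{(2n+1)^2 \pi^2 D t}{4 L^2}\right).}
#'
#' @param D Constant diffusivity, m^2 s^-1.
#' @param L Slab thickness, m.
#' @param t Time(s) since the start of drying, s; vectorized.
#' @param n_terms Number of series terms beyond the first (`n = 0..n_terms`).
#' @return Moisture ratio(s) in (0, 1].
#' @export
analytic_slab_ratio <- function(D, L, t, n_terms = 50) {
  if (!is.numeric(D) || D <= 0 || !is.numeric(L) || L <= 0)
    .stopf("'D' and 'L' must be positive")
  if (any(t < 0)) .stopf("'t' must be non-negative")
  if (n_terms < 1) .stopf("'n_terms' must be >= 1")
  n <- 0:n_terms
  k <- (2 * n + 1)^2
  vapply(t, function(ti) {
    sum(8 / (k * pi^2) * exp(-k * pi^2 * D * ti / (4 * L^2)))
  }, numeric(1))
}
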