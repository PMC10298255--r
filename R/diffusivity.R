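#' Parameters of the effective moisture diffusivity law
#'
#' Bundles the four parameters of the moisture- and temperature-dependent
#' effective diffusivity law
#' \deqn{D_{eff}(M, T) = D_0 \exp\!\left(-\frac{E_a}{R T} + a M - b M^2\right)}
#' used to model drying of thin gel films, where `M` is the local dry-basis
#' moisture content and `T` the absolute temperature. The universal gas
#' constant `R = 8.3145` J mol^-1 K^-1 is fixed internally.
#'
#' The default (`form = "exponent"`) places the moisture polynomial inside
#' the exponent, which keeps the diffusivity strictly positive for any finite
#' moisture and gives it a unique maximum at `M = a/(2b)` when both
#' coefficients are positive. The alternative reading
#' `D0*exp(-Ea/(R*T)) + a*M - b*M^2` is available as `form = "additive"`;
#' because that expression can turn negative at high moisture it is clamped
#' below at `floor`.
#'
#' @param D0 Pre-exponential (Arrhenius) diffusivity, m^2 s^-1; must be > 0.
#' @param Ea Activation energy, J mol^-1; must be >= 0.
#' @param a Linear moisture coefficient, (g/g)^-1.
#' @param b Quadratic moisture coefficient, (g/g)^-2.
#' @param form Which algebraic reading of the law to evaluate.
#' @param floor Lower clamp for the additive form, m^2 s^-1.
#' @return An object of class `deff_params`.
#' @seealso [effective_diffusivity()], [constant_diffusivity()]
#' @examples
#' p <- deff_params(D0 = 1.2e-7, Ea = 2.5e4, a = 0.04, b = 0.025)
#' effective_diffusivity(p, M = 2, T_K = 308.15)
#' @export
deff_params <- function(D0, Ea = 0, a = 0, b = 0,
                        form = c("exponent", "additive"), floor = 1e-14) {
  form <- match.arg(form)
  for (nm in c("D0", "Ea", "a", "b", "floor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      .stopf("'%s' must be a single finite number", nm)
  }
  if (D0 <= 0) .stopf("'D0' must be strictly positive")
  if (Ea < 0) .stopf("'Ea' must be non-negative")
  structure(list(D0 = D0, Ea = Ea, a = a, b = b,
                 form = form, floor = floor),
            class = "deff_params")
}

#' @export
print.deff_params <- function(x, ...) {
  cat(sprintf(
    "Effective-diffusivity parameters (%s form)\n  D0 = %.4g m^2/s, Ea = %.4g J/mol, a = %.4g (g/g)^-1, b = %.4g (g/g)^-2\n",
    x$form, x$D0, x$Ea, x$a, x$b))
  invisible(x)
}

.check_MT <- function(M, T_K) {
  if (!is.numeric(M) || any(!is.finite(M)) || any(M < 0))
    .stopf("moisture content 'M' must be finite and non-negative")
  if (!is.numeric(T_K) || any(!is.finite(T_K)) || any(T_K <= 0))
    .stopf("temperature 'T_K' must be finite and positive (kelvin)")
}

#' Evaluate the effective moisture diffusivity D_eff(M, T)
#'
#' @param params A [deff_params()] object.
#' @param M Dry-basis moisture content, g water per g dry matter; vectorized.
#' @param T_K Absolute temperature, K (recycled against `M`).
#' @return Effective diffusivity in m^2 s^-1, same length as `M`.
#' @export
effective_diffusivity <- function(params, M, T_K) {
  stopifnot(inherits(params, "deff_params"))
  .check_MT(M, T_K)
  arr <- params$D0 * exp(-params$Ea / (.R_GAS * T_K))
  if (params$form == "exponent") {
    arr * exp(params$a * M - params$b * M^2)
  } else {
    pmax(arr + params$a * M - params$b * M^2, params$floor)
  }
}

#' Evaluate the constant (moisture-independent) diffusivity D_eff(T)
#'
#' The Arrhenius-only benchmark `D0 * exp(-Ea/(R*T))`, i.e. the moisture-
#' dependent law with `a = b = 0`. Used by the constant-diffusivity drying
#' model that the variable model is compared against.
#'
#' @inheritParams effective_diffusivity
#' @return Diffusivity in m^2 s^-1.
#' @export
constant_diffusivity <- function(params, T_K) {
  stopifnot(inherits(params, "deff_params"))
  .check_MT(0, T_K)
  params$D0 * exp(-params$Ea / (.R_GAS * T_K))
}

#' Drying air conditions for one experiment
#'
#' @param temperature_c Drying air temperature, degrees Celsius (0-100).
#' @param relative_humidity Relative humidity, percent (0 < RH <= 100).
#' @param equilibrium_moisture Dry-basis equilibrium moisture content `M_e`
#'   of the film in this air, g/g. Not derived from a sorption isotherm;
#'   supplied per condition.
#' @param air_velocity Air speed across the sample, m/s (metadata only).
#' @return An object of class `drying_conditions`.
#' @export
drying_conditions <- function(temperature_c, relative_humidity,
                              equilibrium_moisture, air_velocity = 2) {
  if (!is.numeric(temperature_c) || length(temperature_c) != 1L ||
      !is.finite(temperature_c) || temperature_c < 0 || temperature_c > 100)
    .stopf("'temperature_c' must be a single value in [0, 100] degrees C")
  if (!is.numeric(relative_humidity) || length(relative_humidity) != 1L ||
      !is.finite(relative_humidity) ||
      relative_humidity <= 0 || relative_humidity > 100)
    .stopf("'relative_humidity' must be in (0, 100] percent")
  if (!is.numeric(equilibrium_moisture) || length(equilibrium_moisture) != 1L ||
      !is.finite(equilibrium_moisture) || equilibrium_moisture < 0)
    .stopf("'equilibrium_moisture' must be non-negative")
  structure(list(temperature_c = temperature_c,
                 temperature_k = .kelvin(temperature_c),
                 relative_humidity = relative_humidity,
                 equilibrium_moisture = equilibrium_moisture,
                 air_velocity = air_velocity),
            class = "drying_conditions")
}

#' @export
print.drying_conditions <- function(x, ...) {
  cat(sprintf("Drying conditions: %g degC, RH %g%%, Me = %g g/g, air %g m/s\n",
              x$temperature_c, x$relative_humidity,
              x$equilibrium_moisture, x$air_velocity))
  invisible(x)
}

#' @export
format.drying_conditions <- function(x, ...) {
  sprintf("%gC_RH%g", x$temperature_c, x$relative_humidity)
}
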