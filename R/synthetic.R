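#' The five drying conditions of the study design
#'
#' Three air temperatures (35, 40, 45 degC) at a fixed relative humidity of
#' 60\%, plus relative humidities of 40 and 50\% at 35 degC, all with 2 m/s
#' air flow, in the fixed order (35, RH40), (35, RH50), (35, RH60),
#' (40, RH60), (45, RH60).
#'
#' @param equilibrium_moisture Equilibrium moisture content(s) `M_e`, g/g;
#'   either a single value recycled over all five conditions or one value
#'   per condition.
#' @return A list of five [drying_conditions()] objects.
#' @export
default_conditions <- function(equilibrium_moisture = 0.10) {
  temps <- c(35, 35, 35, 40, 45)
  rhs <- c(40, 50, 60, 60, 60)
  me <- rep_len(equilibrium_moisture, 5L)
  lapply(seq_len(5L), function(i)
    drying_conditions(temps[i], rhs[i], me[i], air_velocity = 2))
}

#' Ground-truth diffusivity parameters of the synthetic experiment
#'
#' The generator's "true" diffusivity law, chosen once to be internally
#' consistent with the study geometry and timetable: with a 0.2 mm film the
#' resulting `D_eff` of roughly 2-8e-12 m^2/s carries the slowest condition
#' (35 degC) from 8.44 g/g to within 6\% of equilibrium over the 140-min
#' window, with the mid-drying knee near 0.5-1 g/g. The positive `a` and
#' `b` give the diffusivity an interior maximum at `M = a/(2b) = 0.8` g/g,
#' reproducing the rise-then-fall of diffusivity with moisture seen in
#' polysaccharide films.
#'
#' @return A [deff_params()] object.
#' @export
default_true_params <- function() {
  deff_params(D0 = 1.2e-7, Ea = 2.5e4, a = 0.04, b = 0.025)
}

#' Configuration of the synthetic drying experiment
#'
#' @param true_params Generating [deff_params()].
#' @param M0 Initial dry-basis moisture, g/g.
#' @param conditions List of [drying_conditions()].
#' @param grid A [shell_grid()].
#' @param sampling_interval Sampling interval, min.
#' @param duration Experiment duration, min.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise; must lie in `[0, 0.1]` (experimental error below
#'   10\%).
#' @param seed Integer seed; recorded in all outputs.
#' @param phantom Phantom-image geometry: list with `size` (px), `r_in`,
#'   `r_out` (annulus radii, px), `pixel_size` (m), `noise_sd_frac`
#'   (background noise as a fraction of the initial mean shell signal) and
#'   `erode` (boundary-pixel erosion of the quantification zone, px).
#' @param preset `"default"` keeps the internally consistent diffusivity
#'   scale; `"reported_scale"` multiplies `D0` by 70 so `D_eff` falls in the
#'   3-7e-10 m^2/s band reported for capsule shells, with a proportionally
#'   shorter 2-min time axis (the two scales cannot coexist at this film
#'   thickness).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(true_params = default_true_params(),
                             M0 = 8.44,
                             conditions = default_conditions(),
                             grid = shell_grid(2e-4, 4),
                             sampling_interval = 20,
                             duration = 140,
                             noise_cv = 0.05,
                             seed = 20230605,
                             phantom = list(size = 64, r_in = 20, r_out = 28,
                                            pixel_size = 1e-4,
                                            noise_sd_frac = 0.01, erode = 1),
                             preset = c("default", "reported_scale")) {
  preset <- match.arg(preset)
  stopifnot(inherits(true_params, "deff_params"),
            inherits(grid, "shell_grid"))
  if (preset == "reported_scale") {
    true_params <- deff_params(true_params$D0 * 70, true_params$Ea,
                               true_params$a, true_params$b,
                               form = true_params$form)
    duration <- 2
    sampling_interval <- 0.25
  }
  if (!is.numeric(sampling_interval) || sampling_interval <= 0)
    .stopf("'sampling_interval' must be positive")
  if (!is.numeric(noise_cv) || noise_cv < 0 || noise_cv > 0.1)
    .stopf("'noise_cv' must lie in [0, 0.1]")
  for (cond in conditions) stopifnot(inherits(cond, "drying_conditions"))
  structure(list(true_params = true_params, M0 = M0,
                 conditions = conditions, grid = grid,
                 sampling_interval = sampling_interval, duration = duration,
                 noise_cv = noise_cv, seed = as.integer(seed),
                 phantom = phantom, preset = preset),
            class = "generator_config")
}

# truncated standard normal on [-3, 3] via inverse-CDF sampling (no
# clipping atoms at the truncation points)
.rtnorm3 <- function(n) {
  qnorm(runif(n, pnorm(-3), pnorm(3)))
}

#' Generate a synthetic multi-condition drying experiment
#'
#' Simulates the true model under every configured condition, samples the
#' average (and per-layer nodal) moisture at the sampling interval, and
#' applies multiplicative truncated-Gaussian noise
#' (`value * (1 + noise_cv * z)`, `z` truncated at +/- 3 sigma) to all
#' samples after `t = 0`, clamped below at the equilibrium moisture. The
#' `t = 0` record reports the initial moisture exactly: initial moisture is
#' a formulation property measured by oven-drying, not a per-scan reading.
#' Output is byte-identical for identical configurations.
#'
#' @param cfg A [generator_config()].
#' @return A list of [drying_curve()] objects (one per condition, each with
#'   per-layer observations in `$layers`), with attributes `config` and
#'   `truth` (the noiseless [simulate_drying()] histories).
#' @export
generate_drying_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  tt_min <- seq(0, cfg$duration, by = cfg$sampling_interval)
  Z <- cfg$grid$Z
  truths <- list()
  curves <- vector("list", length(cfg$conditions))
  for (i in seq_along(cfg$conditions)) {
    cond <- cfg$conditions[[i]]
    hist <- simulate_drying(cfg$M0, cfg$true_params, cond, cfg$grid,
                            t_end = cfg$duration * 60,
                            output_times = tt_min * 60, stop_tol = 0)
    truths[[i]] <- hist
    Me <- cond$equilibrium_moisture
    nt <- length(tt_min)
    avg <- hist$M_avg
    avg[1] <- cfg$M0
    lay <- hist$fields
    if (cfg$noise_cv > 0 && nt > 1L) {
      z_avg <- .rtnorm3(nt - 1L)
      avg[-1] <- pmax(avg[-1] * (1 + cfg$noise_cv * z_avg), Me)
      z_lay <- matrix(.rtnorm3((nt - 1L) * (Z + 1L)), nrow = nt - 1L)
      lay[-1, ] <- pmax(lay[-1, ] * (1 + cfg$noise_cv * z_lay), Me)
    }
    curve <- drying_curve(cond, tt_min, avg, layers = lay,
                          provenance = "synthetic")
    mr_end <- (hist$M_avg[nt] - Me) / (cfg$M0 - Me)
    if (mr_end > 0.5)
      warning(sprintf(
        "condition %s: duration inconsistent with diffusivity (final moisture ratio %.2f > 0.5)",
        format(cond), mr_end))
    curves[[i]] <- curve
  }
  attr(curves, "config") <- cfg
  attr(curves, "truth") <- truths
  curves
}

#' Render a synthetic proton-density phantom series from a moisture history
#'
#' Draws an annular cross-section of the capsule shell on a square image:
#' each shell pixel belongs to the layer node nearest its radius (inner
#' radius = sealed pin side, node `x = 0`; outer radius = air side, node
#' `x = Z`), its hydrogen density is proportional to that node's moisture
#' at the frame time, and the pixel intensity follows the spin-echo signal
#' model. Additive Gaussian background noise is applied to every pixel.
#' The quantification zone is the annulus eroded by `phantom$erode` pixels
#' to drop partial-volume boundary pixels.
#'
#' @param cfg A [generator_config()] (phantom geometry and seed).
#' @param history A [moisture_history()][simulate_drying()] whose snapshots
#'   are at the acquisition times.
#' @param params Spin-echo parameters; hydrogen density is taken as
#'   100 a.u. per unit moisture (g/g).
#' @param seed Seed for the frame noise; defaults to `cfg$seed + 1`.
#' @return An [mri_series()] with zone and layer masks.
#' @export
generate_mri_series <- function(cfg, history,
                                params = mri_sequence_params(),
                                seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "generator_config"),
            inherits(history, "moisture_history"))
  ph <- cfg$phantom
  Z <- history$grid$Z
  if ((ph$r_out - ph$r_in) < Z)
    .stopf("annulus of %g px cannot hold %d layers", ph$r_out - ph$r_in, Z)
  n <- ph$size
  cx <- (n + 1) / 2
  r <- sqrt(outer((seq_len(n) - cx)^2, (seq_len(n) - cx)^2, `+`))
  shell <- r >= ph$r_in & r <= ph$r_out
  layer <- matrix(NA_integer_, n, n)
  layer[shell] <- pmin(pmax(as.integer(
    round((r[shell] - ph$r_in) / ((ph$r_out - ph$r_in) / Z))), 0L), Z)
  zone <- r >= ph$r_in + ph$erode & r <= ph$r_out - ph$erode
  nt <- length(history$times)
  frames <- array(0, dim = c(n, n, nt))
  rho_per_M <- 100
  for (k in seq_len(nt)) {
    img <- matrix(0, n, n)
    img[shell] <- signal_intensity(
      params, rho_H = rho_per_M * history$fields[k, layer[shell] + 1L])
    frames[, , k] <- img
  }
  if (ph$noise_sd_frac > 0) {
    set.seed(as.integer(seed))
    sd0 <- ph$noise_sd_frac * mean(frames[, , 1][shell])
    frames <- frames + array(rnorm(length(frames), sd = sd0), dim(frames))
  }
  mri_series(frames, times_min = history$times / 60,
             pixel_size = ph$pixel_size, zone_mask = zone,
             layer_labels = layer, params = params)
}
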