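#' Spin-echo acquisition parameters
#'
#' Parameters of the proton-density-weighted spin-echo signal model
#' \deqn{I = k\,\rho_H\,(1 - e^{-T_R/T_1})\,e^{-T_E/T_2}} used both to
#' render synthetic phantoms and to reason about acquisition settings. With
#' a long repetition time and short echo time the intensity tracks the
#' hydrogen (water) density, which is why proton-density images quantify
#' moisture.
#'
#' @param k Proportionality constant, arbitrary units.
#' @param TR Repetition time, ms.
#' @param TE Echo time, ms; must be shorter than `TR`.
#' @param T1 Longitudinal relaxation time, ms.
#' @param T2 Transverse relaxation time, ms.
#' @param rho_H Hydrogen density, arbitrary units proportional to m^-3.
#' @return An object of class `mri_sequence_params`.
#' @export
mri_sequence_params <- function(k = 1, TR = 2000, TE = 18.125,
                                T1 = 500, T2 = 50, rho_H = 1) {
  for (nm in c("TR", "TE", "T1", "T2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      .stopf("'%s' must be a single positive time in ms", nm)
  }
  if (TE >= TR) .stopf("echo time TE must be shorter than repetition time TR")
  structure(list(k = k, TR = TR, TE = TE, T1 = T1, T2 = T2, rho_H = rho_H),
            class = "mri_sequence_params")
}

#' Spin-echo signal intensity
#'
#' @param p An [mri_sequence_params()] object.
#' @param rho_H Optional hydrogen density overriding `p$rho_H`; vectorized.
#' @return Signal intensity in arbitrary units.
#' @export
signal_intensity <- function(p, rho_H = NULL) {
  stopifnot(inherits(p, "mri_sequence_params"))
  rho <- if (is.null(rho_H)) p$rho_H else rho_H
  p$k * rho * (1 - exp(-p$TR / p$T1)) * exp(-p$TE / p$T2)
}

#' A time-indexed series of proton-density image frames
#'
#' @param frames 3-D numeric array `ny x nx x nt` of signal intensities, or
#'   a list of equally sized matrices.
#' @param times_min Acquisition times in minutes, strictly increasing with
#'   the first frame at `t = 0`; the final frame is the designated
#'   equilibrium reference.
#' @param pixel_size Pixel edge length, m.
#' @param zone_mask Logical matrix marking the shell zone used for
#'   quantification (nonempty).
#' @param layer_labels Optional integer matrix of per-pixel layer indices
#'   `0..Z` (`NA` outside the shell).
#' @param params The [mri_sequence_params()] used (metadata).
#' @return An object of class `mri_series`.
#' @export
mri_series <- function(frames, times_min, pixel_size, zone_mask,
                       layer_labels = NULL, params = mri_sequence_params()) {
  if (is.list(frames))
    frames <- array(unlist(frames),
                    dim = c(dim(frames[[1]]), length(frames)))
  if (length(dim(frames)) != 3L)
    .stopf("'frames' must be an ny x nx x nt array")
  nt <- dim(frames)[3]
  times_min <- as.numeric(times_min)
  if (length(times_min) != nt)
    .stopf("'times_min' must have one entry per frame")
  if (times_min[1] != 0 || any(diff(times_min) <= 0))
    .stopf("'times_min' must start at 0 and be strictly increasing")
  if (!is.logical(zone_mask) || !any(zone_mask))
    .stopf("'zone_mask' must be a nonempty logical matrix")
  if (!all(dim(zone_mask) == dim(frames)[1:2]))
    .stopf("'zone_mask' dimensions must match the frames")
  if (!is.null(layer_labels) &&
      !all(dim(layer_labels) == dim(frames)[1:2]))
    .stopf("'layer_labels' dimensions must match the frames")
  structure(list(frames = frames, times_min = times_min,
                 pixel_size = pixel_size, zone_mask = zone_mask,
                 layer_labels = layer_labels, params = params),
            class = "mri_series")
}

#' @export
print.mri_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "MRI series: %d frames of %dx%d px (%g m/px), t = %g..%g min, zone %d px\n",
    d[3], d[1], d[2], x$pixel_size, x$times_min[1], x$times_min[d[3]],
    sum(x$zone_mask)))
  invisible(x)
}

# middle third of the shell zone's radial band, by distance from the image
# centre (the few-pixel shells of real acquisitions motivate a fraction,
# not a pixel count)
.middle_zone <- function(series) {
  d <- dim(series$frames)[1:2]
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  r <- sqrt(outer((seq_len(d[1]) - cx)^2, (seq_len(d[2]) - cy)^2, `+`))
  rr <- range(r[series$zone_mask])
  third <- (rr[2] - rr[1]) / 3
  series$zone_mask & r >= rr[1] + third & r <= rr[2] - third
}

.zone_means <- function(series, mask) {
  nt <- dim(series$frames)[3]
  vapply(seq_len(nt), function(k) mean(series$frames[, , k][mask]),
         numeric(1))
}

#' Moisture percentage of a frame relative to the initial and final frames
#'
#' The normalized zone-mean signal
#' \deqn{100 \times \frac{\bar I(t) - \bar I(t_{final})}
#'                       {\bar I(0) - \bar I(t_{final})}}
#' where the bar denotes the mean over the quantification zone. By
#' construction the initial frame scores 100\% and the designated
#' equilibrium (final) frame 0\%; the ratio is invariant under any global
#' affine rescaling of the signal (scanner gain and offset drop out).
#'
#' @param series An [mri_series()].
#' @param t_index Frame index (1-based; frame 1 is `t = 0`).
#' @param zone `"shell"` uses the full zone mask, `"middle"` restricts it to
#'   the middle third of the shell's radial band.
#' @return Moisture percentage (100 at `t = 0`, 0 at equilibrium).
#' @export
moisture_percentage <- function(series, t_index, zone = c("shell", "middle")) {
  stopifnot(inherits(series, "mri_series"))
  zone <- match.arg(zone)
  nt <- dim(series$frames)[3]
  if (t_index < 1 || t_index > nt) .stopf("'t_index' out of range 1..%d", nt)
  mask <- if (zone == "shell") series$zone_mask else .middle_zone(series)
  m <- .zone_means(series, mask)
  den <- m[1] - m[nt]
  if (den == 0)
    .stopf("initial and equilibrium frames have identical zone means")
  100 * (m[t_index] - m[nt]) / den
}

#' Per-layer moisture percentages of a frame
#'
#' Applies the normalized-signal formula of [moisture_percentage()] to each
#' layer zone separately, using that layer's own initial and final means.
#' A layer whose signal never changes between the initial and final frames
#' (e.g. the air-side layer pinned at equilibrium throughout) is reported
#' as 0; with measurement noise such a layer's percentage is dominated by
#' the boundary effect and should not be over-interpreted.
#'
#' @inheritParams moisture_percentage
#' @return Named numeric vector of percentages for layers `0..Z`.
#' @export
layer_profile <- function(series, t_index) {
  stopifnot(inherits(series, "mri_series"))
  if (is.null(series$layer_labels))
    .stopf("series has no layer labels")
  nt <- dim(series$frames)[3]
  if (t_index < 1 || t_index > nt) .stopf("'t_index' out of range 1..%d", nt)
  layers <- sort(unique(series$layer_labels[!is.na(series$layer_labels)]))
  out <- vapply(layers, function(lb) {
    mask <- !is.na(series$layer_labels) & series$layer_labels == lb
    if (!any(mask)) .stopf("layer %d has an empty zone", lb)
    m <- .zone_means(series, mask)
    den <- m[1] - m[nt]
    if (den == 0) {
      if (m[t_index] - m[nt] == 0) return(0)
      .stopf("layer %d: zero denominator with nonzero numerator", lb)
    }
    100 * (m[t_index] - m[nt]) / den
  }, numeric(1))
  names(out) <- paste0("x", layers)
  out
}
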