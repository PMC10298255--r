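# a tiny handmade series: 4x4 frames, full-image zone, linear drying
toy_series <- function(levels = c(10, 7, 4, 1), noise = NULL) {
  frames <- lapply(seq_along(levels), function(k) {
    m <- matrix(levels[k], 4, 4)
    if (!is.null(noise)) m <- m + noise[[k]]
    m
  })
  mri_series(frames, times_min = (seq_along(levels) - 1) * 20,
             pixel_size = 1e-4, zone_mask = matrix(TRUE, 4, 4))
}

test_that("spin-echo signal matches its closed form and limits", {
  p <- mri_sequence_params(k = 1, TR = 2000, TE = 18.125, T1 = 500, T2 = 50)
  # frozen from an arbitrary-precision evaluation of Eq. of the signal model
  expect_equal(signal_intensity(p, rho_H = 100), 68.318783209902493,
               tolerance = 1e-12)
  # saturation limit: TR >> T1 and TE -> 0 gives k * rho
  psat <- mri_sequence_params(k = 2, TR = 1e9, TE = 1e-9, T1 = 500, T2 = 50)
  expect_equal(signal_intensity(psat, rho_H = 10), 20, tolerance = 1e-6)
  # linearity in proton density
  expect_equal(signal_intensity(p, rho_H = 200),
               2 * signal_intensity(p, rho_H = 100))
  expect_error(mri_sequence_params(TR = 100, TE = 200), "shorter")
  expect_error(mri_sequence_params(T1 = -1), "positive")
})

test_that("moisture percentage is 100% initially, 0% at equilibrium, linear between", {
  s <- toy_series(levels = c(10, 7, 5.5, 1))
  n <- length(s$times_min)
  expect_identical(moisture_percentage(s, 1), 100)
  expect_identical(moisture_percentage(s, n), 0)
  # 5.5 is exactly midway between 10 and 1
  expect_equal(moisture_percentage(s, 3), 50)
  expect_error(moisture_percentage(s, 9), "out of range")
  flat <- toy_series(levels = c(3, 3))
  expect_error(moisture_percentage(flat, 1), "identical")
})

test_that("moisture percentage is invariant under affine signal rescaling", {
  set.seed(7)
  noise <- replicate(4, matrix(rnorm(16, sd = 0.2), 4, 4), simplify = FALSE)
  s <- toy_series(noise = noise)
  pct <- vapply(1:4, function(k) moisture_percentage(s, k), numeric(1))
  gained <- mri_series(s$frames * 3.7 + 11, s$times_min, s$pixel_size,
                       s$zone_mask)
  pct2 <- vapply(1:4, function(k) moisture_percentage(gained, k), numeric(1))
  expect_equal(pct2, pct, tolerance = 1e-12)
})

test_that("percentages stay within [0, 100] for monotone zone means", {
  s <- toy_series(levels = c(10, 6, 3, 1))
  pct <- vapply(1:4, function(k) moisture_percentage(s, k), numeric(1))
  expect_true(all(pct >= 0 & pct <= 100))
  expect_true(all(diff(pct) < 0))
})

test_that("layer profile recovers the generating nodal profile from a phantom", {
  cfg <- generator_config(phantom = list(size = 64, r_in = 20, r_out = 28,
                                         pixel_size = 1e-4,
                                         noise_sd_frac = 0, erode = 1))
  cond <- default_conditions()[[3]]
  hist <- simulate_drying(cfg$M0, cfg$true_params, cond, cfg$grid,
                          140 * 60, seq(0, 140, 20) * 60, stop_tol = 0)
  s <- generate_mri_series(cfg, hist)
  nt <- length(s$times_min)
  for (k in c(2, 4, 6)) {
    prof <- layer_profile(s, k)
    # normalized per-node truth: 100 * (M(t) - M(end)) / (M(0) - M(end))
    truth <- 100 * (hist$fields[k, 1:4] - hist$fields[nt, 1:4]) /
      (hist$fields[1, 1:4] - hist$fields[nt, 1:4])
    expect_equal(unname(prof[1:4]), unname(truth), tolerance = 0.02)
  }
  # the pinned air-side layer never changes: reported as 0 by convention
  expect_equal(unname(layer_profile(s, 2)["x4"]), 0)
  # uniform frames give equal percentages in every layer
  u <- s
  for (k in seq_len(nt)) u$frames[, , k] <- (nt - k) / nt
  prof_u <- layer_profile(u, 2)
  expect_true(all(abs(prof_u - prof_u[1]) < 1e-9))
})

test_that("zone percentage round-trips the area-weighted phantom moisture", {
  # the zone mean images layers in proportion to their pixel counts, so the
  # correct round-trip reference is the pixel-area-weighted layer moisture
  # (for an annulus the outer, drier layers carry more area than in the
  # equal-width slab mean)
  cfg <- generator_config()
  cond <- cfg$conditions[[3]]
  hist <- simulate_drying(cfg$M0, cfg$true_params, cond, cfg$grid,
                          140 * 60, seq(0, 140, 20) * 60, stop_tol = 0)
  s <- generate_mri_series(cfg, hist)
  nt <- length(s$times_min)
  px <- table(s$layer_labels[s$zone_mask])
  w <- as.numeric(px) / sum(px)
  Mw <- drop(hist$fields[, as.integer(names(px)) + 1L] %*% w)
  ref <- 100 * (Mw - Mw[nt]) / (Mw[1] - Mw[nt])
  pct <- vapply(seq_len(nt), function(k) moisture_percentage(s, k),
                numeric(1))
  expect_lt(max(abs(pct - ref)), 1.5)  # within the 1% background noise
})

test_that("series constructors validate masks, labels and times", {
  f <- array(1, dim = c(4, 4, 2))
  expect_error(mri_series(f, c(0, 10), 1e-4, matrix(FALSE, 4, 4)),
               "nonempty")
  expect_error(mri_series(f, c(5, 10), 1e-4, matrix(TRUE, 4, 4)),
               "start at 0")
  expect_error(mri_series(f, c(0, 10), 1e-4, matrix(TRUE, 3, 3)),
               "dimensions")
  expect_error(mri_series(f, c(0, 10), 1e-4, matrix(TRUE, 4, 4),
                          layer_labels = matrix(0L, 2, 2)), "dimensions")
  s <- mri_series(f, c(0, 10), 1e-4, matrix(TRUE, 4, 4))
  expect_error(layer_profile(s, 1), "no layer labels")
})
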