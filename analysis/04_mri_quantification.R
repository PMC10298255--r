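#!/usr/bin/env Rscript
# Render a proton-density phantom series from the simulated 35C/RH60
# drying history and quantify it the way LF-MRI drying studies do: zone
# moisture percentage normalized between the initial (100%) and
# equilibrium (0%) frames, plus per-layer percentages across the shell.

suppressPackageStartupMessages(library(capsuledry))

outdir <- "results/mri"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config()
cond <- cfg$conditions[[3]]
tt <- seq(0, cfg$duration, cfg$sampling_interval) * 60
hist <- simulate_drying(cfg$M0, cfg$true_params, cond, cfg$grid,
                        max(tt), tt, stop_tol = 0)
series <- generate_mri_series(cfg, hist)
write_mri_series(series, file.path(outdir, "phantom"))

nt <- length(series$times_min)
quant <- data.frame(
  time_min = series$times_min,
  moisture_pct = vapply(seq_len(nt), function(k)
    moisture_percentage(series, k), numeric(1)),
  moisture_pct_middle = vapply(seq_len(nt), function(k)
    moisture_percentage(series, k, zone = "middle"), numeric(1)))
layers <- t(vapply(seq_len(nt), function(k) layer_profile(series, k),
                   numeric(length(layer_profile(series, 1)))))
quant <- cbind(quant, as.data.frame(layers))
write.table(quant, file.path(outdir, "phantom_quantification.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cat("Phantom:", nt, "frames,", sum(series$zone_mask), "zone pixels\n")
print(round(quant[, 1:3], 2), row.names = FALSE)
# reference the zone mean actually images: layers weighted by their pixel
# counts (an annulus gives the outer, drier layers more area than the
# equal-width slab mean does)
px <- table(series$layer_labels[series$zone_mask])
w <- as.numeric(px) / sum(px)
Mw <- drop(hist$fields[, as.integer(names(px)) + 1L] %*% w)
mr_area <- 100 * (Mw - Mw[nt]) / (Mw[1] - Mw[nt])
mr_slab <- 100 * (hist$M_avg - hist$M_avg[nt]) / (hist$M_avg[1] - hist$M_avg[nt])
cat(sprintf("\nMax |image %% - area-weighted moisture ratio %%| = %.2f points\n",
            max(abs(quant$moisture_pct - mr_area))))
cat(sprintf("Max |image %% - slab-average moisture ratio %%|  = %.2f points\n",
            max(abs(quant$moisture_pct - mr_slab))))
cat("The image percentage reproduces the area-weighted zone moisture to\n",
    "within the 1% background noise; its offset from the slab average is\n",
    "the annulus geometry (outer, drier layers carry more pixels), not\n",
    "a quantification error. Endpoints are exactly 100% and 0% by\n",
    "construction of the normalization.\n")
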