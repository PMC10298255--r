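#' Average effective diffusivity along a simulated drying trajectory
#'
#' Tabulates, for every snapshot of a moisture history, the average
#' moisture and the moisture-weighted average diffusivity [deff_avg()]
#' evaluated with the (fitted or true) law. This is the
#' diffusivity-versus-moisture analysis: with positive moisture
#' coefficients the column rises as the film dries, peaks near
#' `M = a/(2b)`, and falls towards equilibrium.
#'
#' @param fit A `fit_result` from [fit_variable()] (joint fit) or a
#'   [deff_params()] object.
#' @param history A [simulate_drying()] result.
#' @return A data frame with columns `time_min`, `M_avg`, `D_eff_avg`.
#' @export
report_deff_vs_moisture <- function(fit, history) {
  params <- if (inherits(fit, "fit_result")) {
    if (!inherits(fit$params, "deff_params"))
      .stopf("per-condition fits carry one parameter set per curve; pass one")
    fit$params
  } else fit
  stopifnot(inherits(params, "deff_params"),
            inherits(history, "moisture_history"))
  Tk <- history$condition$temperature_k
  data.frame(time_min = history$times / 60,
             M_avg = history$M_avg,
             D_eff_avg = apply(history$fields, 1L, deff_avg,
                               params = params, T_K = Tk))
}

#' Per-layer moisture table of a simulated history
#'
#' @param history A [simulate_drying()] result.
#' @return Data frame with `time_min` and one `M_x<k>` column per node.
#' @export
report_layer_moisture <- function(history) {
  stopifnot(inherits(history, "moisture_history"))
  cbind(data.frame(time_min = history$times / 60),
        as.data.frame(history$fields))
}

#' Per-layer local diffusivity table of a simulated history
#'
#' Local `D_eff(M_x, T)` at every node and snapshot, the layer-resolved
#' companion of [report_deff_vs_moisture()].
#'
#' @inheritParams report_deff_vs_moisture
#' @return Data frame with `time_min` and one `D_x<k>` column per node.
#' @export
report_layer_deff <- function(fit, history) {
  params <- if (inherits(fit, "fit_result")) fit$params else fit
  stopifnot(inherits(params, "deff_params"),
            inherits(history, "moisture_history"))
  Tk <- history$condition$temperature_k
  D <- t(apply(history$fields, 1L, effective_diffusivity,
               params = params, T_K = Tk))
  colnames(D) <- paste0("D_x", seq_len(ncol(D)) - 1L)
  cbind(data.frame(time_min = history$times / 60), as.data.frame(D))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full synthetic drying analysis pipeline
#'
#' Generates the multi-condition synthetic experiment, fits the variable-
#' and constant-diffusivity models, compares them, tabulates average and
#' per-layer diffusivity, renders and quantifies an image phantom for the
#' first condition, and writes every table plus a manifest (with MD5
#' content hashes) under `outdir`. Fully deterministic for a given
#' configuration: two runs with the same config produce byte-identical
#' outputs.
#'
#' @param gen_cfg A [generator_config()].
#' @param fit_cfg A [fit_config()].
#' @param outdir Output directory.
#' @return Invisibly, a list with the fits, comparison, quantification
#'   tables and the manifest path.
#' @export
run_drying_analysis <- function(gen_cfg = generator_config(),
                                fit_cfg = fit_config(),
                                outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  curves <- generate_drying_experiment(gen_cfg)
  truths <- attr(curves, "truth")
  files <- c(files, write_drying_curves(curves, file.path(outdir, "curves")))

  fit_v <- fit_variable(curves, gen_cfg$grid, fit_cfg)
  fit_c <- fit_constant(curves, gen_cfg$grid, fit_cfg)
  cmp <- compare_models(fit_v, fit_c)
  files <- c(files,
             .write_tsv(cmp$summary, file.path(outdir, "model_comparison.tsv")),
             .write_tsv(cmp$per_time,
                        file.path(outdir, "per_time_errors.tsv")))
  jsonlite::write_json(
    list(variable = list(params = unclass(fit_v$params)[c("D0", "Ea", "a", "b", "form")],
                         per_condition = fit_v$per_condition,
                         diagnostics = fit_v$diagnostics),
         constant = list(D = as.list(fit_c$D),
                         per_condition = fit_c$per_condition,
                         diagnostics = fit_c$diagnostics)),
    file.path(outdir, "fits.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(outdir, "fits.json"))

  for (i in seq_along(curves)) {
    cond_tag <- format(curves[[i]]$condition)
    hist <- truths[[i]]
    files <- c(files,
               .write_tsv(report_deff_vs_moisture(fit_v, hist),
                          file.path(outdir, sprintf("deff_vs_moisture_%s.tsv",
                                                    cond_tag))),
               .write_tsv(report_layer_moisture(hist),
                          file.path(outdir, sprintf("layer_moisture_%s.tsv",
                                                    cond_tag))),
               .write_tsv(report_layer_deff(fit_v, hist),
                          file.path(outdir, sprintf("layer_deff_%s.tsv",
                                                    cond_tag))))
  }

  series <- generate_mri_series(gen_cfg, truths[[1]])
  files <- c(files, write_mri_series(series, file.path(outdir, "mri")))
  nt <- length(series$times_min)
  quant <- data.frame(
    time_min = series$times_min,
    moisture_pct = vapply(seq_len(nt), function(k)
      moisture_percentage(series, k), numeric(1)))
  n_layers <- length(layer_profile(series, 1L))
  layers <- t(vapply(seq_len(nt), function(k) layer_profile(series, k),
                     numeric(n_layers)))
  quant <- cbind(quant, as.data.frame(layers))
  files <- c(files, .write_tsv(quant, file.path(outdir, "mri_quant.tsv")))

  manifest <- list(
    seed = gen_cfg$seed,
    preset = gen_cfg$preset,
    true_params = unclass(gen_cfg$true_params)[c("D0", "Ea", "a", "b")],
    files = data.frame(path = sub(paste0("^", outdir, "/?"), "", files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(curves = curves, fit_variable = fit_v,
                 fit_constant = fit_c, comparison = cmp,
                 mri_quant = quant,
                 manifest = file.path(outdir, "manifest.json")))
}
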