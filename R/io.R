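#' Write drying curves to delimited text with JSON sidecars
#'
#' Each curve becomes `curve_<i>_<cond>.tsv` (columns `time_min`, `M_avg`
#' and, when present, per-layer columns `M_x0..M_xZ`) plus a matching
#' `.json` sidecar holding the condition, provenance and initial moisture.
#'
#' @param curves List of [drying_curve()] objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths of the files written.
#' @export
write_drying_curves <- function(curves, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    stem <- file.path(dir, sprintf("curve_%d_%s", i, format(cv$condition)))
    df <- data.frame(time_min = cv$times_min, M_avg = cv$M_avg)
    if (!is.null(cv$layers)) df <- cbind(df, as.data.frame(cv$layers))
    write.table(df, paste0(stem, ".tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
    meta <- list(condition = unclass(cv$condition),
                 provenance = cv$provenance,
                 n_layers = if (is.null(cv$layers)) 0L else ncol(cv$layers))
    jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, paste0(stem, ".tsv"), paste0(stem, ".json"))
  }
  invisible(paths)
}

#' Read drying curves written by [write_drying_curves()]
#'
#' @param dir Directory containing `curve_*.tsv` / `curve_*.json` pairs.
#' @return A list of [drying_curve()] objects, in file order.
#' @export
read_drying_curves <- function(dir) {
  tsvs <- sort(list.files(dir, pattern = "^curve_.*\\.tsv$",
                          full.names = TRUE))
  if (length(tsvs) == 0L) .stopf("no curve files found in '%s'", dir)
  lapply(tsvs, function(tsv) {
    meta <- jsonlite::read_json(sub("\\.tsv$", ".json", tsv),
                                simplifyVector = TRUE)
    df <- read.table(tsv, header = TRUE, sep = "\t")
    cond <- drying_conditions(meta$condition$temperature_c,
                              meta$condition$relative_humidity,
                              meta$condition$equilibrium_moisture,
                              meta$condition$air_velocity)
    lay <- if (meta$n_layers > 0)
      as.matrix(df[, grep("^M_x", names(df)), drop = FALSE]) else NULL
    drying_curve(cond, df$time_min, df$M_avg, layers = lay,
                 provenance = meta$provenance)
  })
}

#' Write a moisture history as delimited text plus a JSON header
#'
#' @param history A [simulate_drying()] result.
#' @param stem Output path without extension; writes `<stem>.tsv` and
#'   `<stem>.json`.
#' @return Invisibly, the two paths.
#' @export
write_moisture_history <- function(history, stem) {
  stopifnot(inherits(history, "moisture_history"))
  df <- data.frame(time_min = history$times / 60, M_avg = history$M_avg)
  df <- cbind(df, as.data.frame(history$fields))
  write.table(df, paste0(stem, ".tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  meta <- list(grid = unclass(history$grid)[c("L", "Z", "dl")],
               condition = unclass(history$condition),
               scheme = history$scheme)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paste0(stem, ".tsv"), paste0(stem, ".json")))
}

#' Write an MRI series as per-frame text matrices (or TIFF) with a sidecar
#'
#' Frames go to `frame_<k>.txt` (whitespace-delimited matrices) or 16-bit
#' grayscale `frame_<k>.tif`; the zone mask and layer labels are written as
#' text matrices, and `series.json` records times, pixel size, file names
#' and sequence parameters.
#'
#' @param series An [mri_series()].
#' @param dir Output directory.
#' @param format `"txt"` (default) or `"tiff"` (requires the tiff package;
#'   intensities are rescaled to the 16-bit range).
#' @return Invisibly, the paths written.
#' @export
write_mri_series <- function(series, dir, format = c("txt", "tiff")) {
  stopifnot(inherits(series, "mri_series"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- dim(series$frames)[3]
  frame_files <- character(nt)
  smax <- max(series$frames)
  for (k in seq_len(nt)) {
    if (format == "txt") {
      frame_files[k] <- sprintf("frame_%02d.txt", k)
      write.table(series$frames[, , k], file.path(dir, frame_files[k]),
                  row.names = FALSE, col.names = FALSE)
    } else {
      if (!requireNamespace("tiff", quietly = TRUE))
        .stopf("the 'tiff' package is required for format = \"tiff\"")
      frame_files[k] <- sprintf("frame_%02d.tif", k)
      tiff::writeTIFF(pmax(series$frames[, , k], 0) / smax,
                      file.path(dir, frame_files[k]), bits.per.sample = 16L)
    }
  }
  write.table(series$zone_mask * 1L, file.path(dir, "zone_mask.txt"),
              row.names = FALSE, col.names = FALSE)
  ll <- series$layer_labels
  if (!is.null(ll)) {
    ll[is.na(ll)] <- -1L
    write.table(ll, file.path(dir, "layer_labels.txt"),
                row.names = FALSE, col.names = FALSE)
  }
  meta <- list(times_min = series$times_min,
               pixel_size_m = series$pixel_size,
               zone_mask_file = "zone_mask.txt",
               layer_labels_file = if (is.null(ll)) NULL else
                 "layer_labels.txt",
               frame_files = frame_files, format = format,
               intensity_scale = if (format == "tiff") smax else 1,
               sequence_params = unclass(series$params))
  jsonlite::write_json(meta, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, c(frame_files, "zone_mask.txt", "series.json")))
}

#' Read an MRI series written by [write_mri_series()]
#'
#' @param dir Directory containing `series.json` and the frame files.
#' @return An [mri_series()].
#' @export
read_mri_series <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "series.json"),
                              simplifyVector = TRUE)
  frames <- lapply(meta$frame_files, function(f) {
    if (grepl("\\.tif$", f)) {
      if (!requireNamespace("tiff", quietly = TRUE))
        .stopf("the 'tiff' package is required to read TIFF frames")
      tiff::readTIFF(file.path(dir, f)) * meta$intensity_scale
    } else {
      as.matrix(read.table(file.path(dir, f)))
    }
  })
  zone <- unname(as.matrix(read.table(file.path(dir,
                                                meta$zone_mask_file)))) == 1L
  ll <- NULL
  if (!is.null(meta$layer_labels_file)) {
    ll <- unname(as.matrix(read.table(file.path(dir,
                                                meta$layer_labels_file))))
    ll[ll < 0] <- NA_integer_
    storage.mode(ll) <- "integer"
  }
  p <- meta$sequence_params
  mri_series(frames, meta$times_min, meta$pixel_size_m, zone,
             layer_labels = ll,
             params = mri_sequence_params(p$k, p$TR, p$TE, p$T1, p$T2,
                                          p$rho_H))
}
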