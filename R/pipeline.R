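#' Process one scene bundle into per-ROI index records
#'
#' The measurement stage of the pipeline: reads the white standard off the
#' RGB image, normalizes channels, computes the six RGB indices per pixel,
#' the NDVI and PRI maps from the cube, and Fv/Fm from the fluorescence
#' maps; segments plant pixels; and averages every index over plant pixels
#' within each ROI.
#'
#' @param bundle a [render_scene()] bundle (or an equivalent list read back
#'   from disk).
#' @param mask segmentation mode: `"ndvi"` (species NDVI threshold, the
#'   default), `"rgb"` (the standard pea/wheat score windows) or `"truth"`
#'   (the generator's ground-truth mask, available for synthetic scenes
#'   only).
#' @param rois optional `roi_set` overriding the default grid over the
#'   bundle's plant region.
#' @param per_pixel compute indices per pixel and then average (the default,
#'   the standard convention); `FALSE` averages channels per ROI
#'   first and computes indices from the averages (sensitivity analysis
#'   only).
#' @param normalize divide RGB channels by the white-standard means before
#'   index computation (default TRUE).
#' @param quiet suppress the per-scene log line.
#' @return Data frame with one row per ROI: `species`, `treatment`, `day`,
#'   `roi`, the six RGB indices, `NDVI`, `PRI`, `FvFm`.
#' @export
process_bundle <- function(bundle, mask = c("ndvi", "rgb", "truth"),
                           rois = NULL, per_pixel = TRUE, normalize = TRUE,
                           quiet = FALSE) {
  mask <- match.arg(mask)
  species <- bundle$meta$species
  d <- dim(bundle$rgb)
  if (is.null(rois)) {
    region <- if (!is.null(bundle$layout)) bundle$layout$plant_region else NULL
    n <- if (!is.null(bundle$layout)) bundle$layout$n_rois else 10
    rois <- default_rois(d[1:2], n = n, region = region)
  }

  ndvi_map <- ndvi(bundle$cube, bundle$wavelengths)
  pri_map <- pri(bundle$cube, bundle$wavelengths)
  fvfm_map <- fv_fm(bundle$f0_map, bundle$fm_map)

  pm <- switch(mask,
    ndvi = ndvi_plant_mask(ndvi_map, species),
    rgb = rgb_plant_mask(bundle$rgb, species),
    truth = {
      if (is.null(bundle$truth_mask)) {
        stop("bundle carries no ground-truth mask")
      }
      structure(bundle$truth_mask, provenance = "truth")
    })

  R <- bundle$rgb[, , 1]; G <- bundle$rgb[, , 2]; B <- bundle$rgb[, , 3]
  if (normalize) {
    white <- white_stats(bundle$rgb, bundle$white_patch)
    ch <- normalize_channels(R, G, B, white)
  } else {
    ch <- list(R = R, G = G, B = B)
  }

  if (per_pixel) {
    idx <- suppressMessages(rgb_indices(ch$R, ch$G, ch$B))
    maps <- c(idx, list(NDVI = ndvi_map, PRI = pri_map, FvFm = fvfm_map))
    vals <- suppressWarnings(lapply(maps, roi_average, mask = pm, rois = rois))
  } else {
    mean_ch <- suppressWarnings(lapply(ch, roi_average, mask = pm, rois = rois))
    idx <- suppressMessages(rgb_indices(mean_ch$R, mean_ch$G, mean_ch$B))
    vals <- c(idx, suppressWarnings(list(
      NDVI = roi_average(ndvi_map, pm, rois),
      PRI = roi_average(pri_map, pm, rois),
      FvFm = roi_average(fvfm_map, pm, rois))))
  }

  rec <- data.frame(species = species, treatment = bundle$meta$treatment,
                    day = bundle$meta$day, roi = rois$label,
                    stringsAsFactors = FALSE)
  for (v in names(vals)) rec[[v]] <- unname(vals[[v]])
  n_empty <- sum(is.na(rec$NDVI))
  if (!quiet) {
    message(sprintf(
      "processed %s/%s day %g: %d plant px (%s mask), %d ROI(s), %d empty",
      species, bundle$meta$treatment, bundle$meta$day, sum(pm),
      attr(pm, "provenance") %||% mask, nrow(rois), n_empty))
  }
  rec
}

#' Simulate a synthetic experiment to disk
#'
#' Writes one scene directory per (species, treatment, day): the RGB image as
#' PNG, the reflectance cube as ENVI header + binary, the fluorescence maps
#' and ROI grid as CSV, the ground-truth mask as PNG, plus a top-level
#' `manifest.csv` and the fully resolved `config.txt`.
#'
#' @param out_dir output directory (created if missing).
#' @param config from [experiment_config()].
#' @param seed base integer seed.
#' @param quiet suppress log lines.
#' @return Invisibly, the manifest data frame (with a `path` column).
#' @export
pipeline_simulate <- function(out_dir, config = experiment_config(),
                              seed = 1, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exp <- generate_experiment(config, seed = seed)
  manifest <- exp$manifest
  manifest$path <- file.path("scenes", manifest$scene_id)
  for (i in seq_along(exp$bundles)) {
    b <- exp$bundles[[i]]
    dir <- file.path(out_dir, manifest$path[i])
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_rgb(b$rgb, file.path(dir, "rgb.png"))
    write_cube(b$cube, b$wavelengths, file.path(dir, "cube.raw"))
    write_matrix_csv(b$f0_map, file.path(dir, "f0.csv"))
    write_matrix_csv(b$fm_map, file.path(dir, "fm.csv"))
    write_rgb(matrix(255L * b$truth_mask, nrow(b$truth_mask)),
              file.path(dir, "truth_mask.png"))
    wp <- b$white_patch
    writeLines(sprintf("white_patch = %d,%d,%d,%d", wp[1], wp[2], wp[3], wp[4]),
               file.path(dir, "white_patch.txt"))
    if (!quiet) message("simulated ", manifest$scene_id[i])
  }
  rois <- default_rois(c(config$layout$height, config$layout$width),
                       n = config$layout$n_rois,
                       region = config$layout$plant_region)
  write_rois(rois, file.path(out_dir, "rois.csv"))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  write_config(list(
    species = config$species, treatments = config$treatments,
    days = config$days, seed = seed,
    height = config$layout$height, width = config$layout$width,
    bands = manifest$bands[1],
    noise_sd = config$opts$noise_sd,
    state_jitter_sd = config$opts$state_jitter_sd,
    fvfm_ceiling = config$opts$fvfm_ceiling
  ), file.path(out_dir, "config.txt"))
  invisible(manifest)
}

# read one simulated scene directory back into a bundle-shaped list
read_scene_dir <- function(dir, species, treatment, day) {
  cube <- read_cube(file.path(dir, "cube.raw"))
  wp_txt <- read_config(file.path(dir, "white_patch.txt"))$white_patch
  wp <- rect(as.integer(wp_txt[1]), as.integer(wp_txt[2]),
             as.integer(wp_txt[3]), as.integer(wp_txt[4]))
  tm <- read_rgb(file.path(dir, "truth_mask.png"))
  list(
    rgb = read_rgb(file.path(dir, "rgb.png")),
    cube = cube$cube, wavelengths = cube$wavelengths,
    f0_map = read_matrix_csv(file.path(dir, "f0.csv")),
    fm_map = read_matrix_csv(file.path(dir, "fm.csv")),
    truth_mask = tm > 127,
    white_patch = wp, layout = NULL,
    meta = list(species = species, treatment = treatment, day = day)
  )
}

#' Process a simulated dataset into an index-record table
#'
#' Reads every scene listed in a dataset's manifest, runs [process_bundle()]
#' and writes the combined per-ROI records as CSV. Deterministic: re-running
#' on identical inputs reproduces the file byte for byte.
#'
#' @param in_dir dataset directory written by [pipeline_simulate()].
#' @param out_csv output CSV path (default `records.csv` inside `in_dir`).
#' @param mask segmentation mode, see [process_bundle()].
#' @param roi_file optional ROI CSV overriding the dataset's grid.
#' @param quiet suppress log lines.
#' @return Invisibly, the records data frame.
#' @export
pipeline_process <- function(in_dir, out_csv = file.path(in_dir, "records.csv"),
                             mask = c("ndvi", "rgb", "truth"),
                             roi_file = NULL, quiet = FALSE) {
  mask <- match.arg(mask)
  manifest_path <- file.path(in_dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop("no manifest.csv in ", in_dir, "; not a simulated dataset?")
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  rois <- if (!is.null(roi_file)) {
    read_rois(roi_file)
  } else if (file.exists(file.path(in_dir, "rois.csv"))) {
    read_rois(file.path(in_dir, "rois.csv"))
  } else NULL
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    b <- read_scene_dir(file.path(in_dir, manifest$path[i]),
                        manifest$species[i], manifest$treatment[i],
                        manifest$day[i])
    process_bundle(b, mask = mask, rois = rois, quiet = quiet)
  })
  records <- do.call(rbind, recs)
  utils::write.csv(format(records, digits = 15, trim = TRUE), out_csv,
                   row.names = FALSE, quote = FALSE)
  invisible(records)
}

#' Calibrate regression models from an index-record table
#'
#' Fits [rgb_calibration()] and writes `models.csv` and `correlations.csv`.
#'
#' @param records_csv records CSV from [pipeline_process()] (or a records
#'   data frame).
#' @param out_dir directory for the two output tables.
#' @param r2_floor flag threshold on R^2.
#' @return Invisibly, the `rgb_calibration` object.
#' @export
pipeline_calibrate <- function(records_csv, out_dir = dirname(records_csv),
                               r2_floor = 0.7) {
  records <- if (is.character(records_csv)) {
    utils::read.csv(records_csv, stringsAsFactors = FALSE)
  } else records_csv
  cal <- rgb_calibration(records, r2_floor = r2_floor)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cal$models, file.path(out_dir, "models.csv"),
                   row.names = FALSE)
  ct <- cal$correlations
  ct$stars <- ifelse(ct$significant, "*", "")
  utils::write.csv(ct, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  invisible(cal)
}

#' Estimate NDVI, PRI and Fv/Fm from RGB-index values
#'
#' Applies fitted calibration lines to new RGB-index observations and writes
#' the predictions.
#'
#' @param models_csv `models.csv` from [pipeline_calibrate()] (or an
#'   `rgb_calibration` object).
#' @param newdata_csv CSV (or data frame) with `species` and the chosen
#'   index column.
#' @param out_csv output path for the prediction table.
#' @param index RGB index to use as the regressor.
#' @return Invisibly, the prediction data frame.
#' @export
pipeline_estimate <- function(models_csv, newdata_csv, out_csv, index = "ExG") {
  models <- if (is.character(models_csv)) {
    utils::read.csv(models_csv, stringsAsFactors = FALSE)
  } else if (inherits(models_csv, "rgb_calibration")) {
    models_csv$models
  } else models_csv
  fake <- structure(list(models = models), class = "rgb_calibration")
  newdata <- if (is.character(newdata_csv)) {
    utils::read.csv(newdata_csv, stringsAsFactors = FALSE)
  } else newdata_csv
  preds <- predict(fake, newdata, index = index)
  utils::write.csv(format(preds, digits = 15, trim = TRUE), out_csv,
                   row.names = FALSE, quote = FALSE)
  invisible(preds)
}
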