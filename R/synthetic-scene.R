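#' Pigment state of a synthetic leaf
#'
#' The scene generator drives leaf optics and fluorescence from three latent
#' variables, each relative to an unstressed plant: `chl` (chlorophyll
#' content), `car` (carotenoid content) and `vitality` (photosynthetic health,
#' which sets Fv/Fm through a configurable ceiling). A healthy control plant
#' has all three equal to 1.
#'
#' @param chl,car,vitality numbers in `[0, 1]`.
#' @return A list of class `"pigment_state"`.
#' @export
pigment_state <- function(chl = 1, car = 1, vitality = 1) {
  vals <- c(chl = chl, car = car, vitality = vitality)
  if (anyNA(vals) || any(vals < 0) || any(vals > 1)) {
    stop("pigment state components must lie in [0, 1]")
  }
  structure(list(chl = chl, car = car, vitality = vitality),
            class = "pigment_state")
}

#' @export
print.pigment_state <- function(x, ...) {
  cat(sprintf("<pigment_state> chl=%.3f car=%.3f vitality=%.3f\n",
              x$chl, x$car, x$vitality))
  invisible(x)
}

#' Stress scenario: species, treatment and measurement days
#'
#' Encodes one experimental arm of the emulated greenhouse design: pea or
#' wheat under control, progressive soil drought, or NaCl irrigation at 100,
#' 200 or 400 mM, observed on a fixed grid of measurement days.
#'
#' @param species `"pea"` or `"wheat"`.
#' @param treatment one of `"control"`, `"drought"`, `"nacl100"`, `"nacl200"`,
#'   `"nacl400"`.
#' @param days ordered vector of measurement days (default the study grid
#'   1, 3, 5, 8, 10, 12).
#' @param onset first day on which the treatment produces an effect; defaults
#'   to 3 for drought and 1 for NaCl treatments (control ignores it).
#' @return A list of class `"stress_scenario"`.
#' @export
stress_scenario <- function(species = c("pea", "wheat"),
                            treatment = c("control", "drought",
                                          "nacl100", "nacl200", "nacl400"),
                            days = c(1, 3, 5, 8, 10, 12),
                            onset = NULL) {
  species <- match.arg(species)
  treatment <- match.arg(treatment)
  if (length(days) < 1 || is.unsorted(days, strictly = TRUE) || any(days < 0)) {
    stop("days must be a strictly increasing vector of non-negative numbers")
  }
  if (is.null(onset)) onset <- if (treatment == "drought") 3 else 1
  structure(list(species = species, treatment = treatment,
                 days = days, onset = onset),
            class = "stress_scenario")
}

#' @export
print.stress_scenario <- function(x, ...) {
  cat(sprintf("<stress_scenario> %s / %s, days {%s}, onset day %g\n",
              x$species, x$treatment, paste(x$days, collapse = ","), x$onset))
  invisible(x)
}

# Day-12 vitality targets, chosen so the simulated Fv/Fm time courses end
# where the emulated study's do (ceiling 0.8): pea drought ~0.2, wheat
# drought ~0.1, pea NaCl400 ~0.25, wheat NaCl 100/200/400 ~0.5/0.4/0.3,
# with 100 and 200 mM only mildly affecting pea.
.vitality_day12 <- list(
  pea   = c(drought = 0.25,  nacl100 = 0.9375, nacl200 = 0.90, nacl400 = 0.3125),
  wheat = c(drought = 0.125, nacl100 = 0.625,  nacl200 = 0.50, nacl400 = 0.375)
)

#' Latent pigment trajectory under stress
#'
#' Maps a scenario and a measurement day to a [pigment_state()]. Controls stay
#' at (1, 1, 1) up to a configurable drift. Stressed arms decay exponentially
#' in the days elapsed since the scenario's onset day, with rates ordered
#' NaCl 100 <= 200 <= 400 and drought the strongest stressor. Chlorophyll
#' decays faster than carotenoids under drought and at an equal rate under
#' salinity, reproducing the different pigment-degradation regimes the two
#' stressors are reported to induce.
#'
#' @param scenario a [stress_scenario()].
#' @param day measurement day; must be one of `scenario$days`.
#' @param drift control-arm drift amplitude (default 0: exact controls).
#' @return A [pigment_state()].
#' @export
stress_trajectory <- function(scenario, day, drift = 0) {
  stopifnot(inherits(scenario, "stress_scenario"))
  if (!day %in% scenario$days) {
    stop(sprintf("day %g is not a measurement day of this scenario", day))
  }
  if (scenario$treatment == "control") {
    lvl <- max(0, min(1, 1 - drift * (1 - cos(day)) / 2))
    return(pigment_state(lvl, lvl, lvl))
  }
  targets <- .vitality_day12[[scenario$species]]
  v12 <- targets[[scenario$treatment]]
  # rate calibrated so vitality reaches its day-12 target after
  # (12 - onset + 1) effective days of stress
  t_ref <- 12 - scenario$onset + 1
  rate_v <- -log(v12) / t_ref
  t_eff <- max(0, day - scenario$onset + 1)
  # pigment decay relative to vitality decay
  if (scenario$treatment == "drought") {
    f_chl <- 0.55; f_car <- 0.35
  } else {
    f_chl <- 0.45; f_car <- 0.45
  }
  pigment_state(chl = exp(-f_chl * rate_v * t_eff),
                car = exp(-f_car * rate_v * t_eff),
                vitality = exp(-rate_v * t_eff))
}

#' Renderer optical parameters
#'
#' The leaf model is a flat visible baseline rising through a sigmoid red edge
#' to a near-infrared plateau, attenuated multiplicatively by Gaussian
#' absorption wells: two chlorophyll wells (430 nm, and a two-sided well at
#' 680 nm that is broad toward the green and narrow toward the NIR, mimicking
#' the sharp red edge) and one carotenoid well at 470 nm. Well depths scale
#' with the pigment state, so pigment loss raises reflectance, most strongly
#' in the red and blue.
#'
#' @param nir_plateau NIR baseline reflectance (default 0.5).
#' @param vis_base visible baseline reflectance of a fully depigmented leaf.
#' @param red_edge,red_edge_width sigmoid red-edge position and width (nm).
#' @param chl_well_680,chl_well_430,car_well_470 well depths (attenuation
#'   exponents at the well centre for a fully pigmented leaf).
#' @param sigma_680_left,sigma_680_right,sigma_430,sigma_470 well widths (nm).
#' @param fvfm_ceiling Fv/Fm of a fully healthy plant (default 0.8).
#' @param noise_sd multiplicative lognormal pixel-noise sd (default 0.05).
#' @param state_jitter_sd per-pixel pigment-state jitter sd (default 0.03);
#'   gives ratio indices realistic pixel-to-pixel variance (pure
#'   multiplicative reflectance noise cancels in every ratio index).
#' @return A named list of renderer options.
#' @export
render_options <- function(nir_plateau = 0.5, vis_base = 0.32,
                           red_edge = 715, red_edge_width = 12,
                           chl_well_680 = 1.9, chl_well_430 = 2.2,
                           car_well_470 = 1.6,
                           sigma_680_left = 60, sigma_680_right = 30,
                           sigma_430 = 40, sigma_470 = 25,
                           fvfm_ceiling = 0.8,
                           noise_sd = 0.05, state_jitter_sd = 0.03) {
  as.list(environment())
}

#' Synthetic leaf reflectance spectrum
#'
#' @param state a [pigment_state()].
#' @param wavelengths wavelengths in nm, all within `[400, 1000]`.
#' @param opts renderer options from [render_options()].
#' @return Reflectance vector in `(0, 1]`, one value per wavelength.
#' @examples
#' wl <- seq(400, 1000, by = 3)
#' healthy <- leaf_reflectance(pigment_state(1, 1, 1), wl)
#' @export
leaf_reflectance <- function(state, wavelengths, opts = render_options()) {
  stopifnot(inherits(state, "pigment_state"))
  if (length(wavelengths) == 0 ||
      any(wavelengths < 400) || any(wavelengths > 1000)) {
    stop("wavelengths must lie within [400, 1000] nm")
  }
  wl <- as.numeric(wavelengths)
  base <- opts$vis_base + (opts$nir_plateau - opts$vis_base) /
    (1 + exp(-(wl - opts$red_edge) / opts$red_edge_width))
  # two-sided Gaussian: broad shoulder into the green, sharp red edge
  s680 <- ifelse(wl <= 680, opts$sigma_680_left, opts$sigma_680_right)
  well680 <- exp(-(wl - 680)^2 / (2 * s680^2))
  well430 <- exp(-(wl - 430)^2 / (2 * opts$sigma_430^2))
  well470 <- exp(-(wl - 470)^2 / (2 * opts$sigma_470^2))
  atten <- state$chl * (opts$chl_well_680 * well680 +
                        opts$chl_well_430 * well430) +
           state$car * opts$car_well_470 * well470
  r <- base * exp(-atten)
  pmin(pmax(r, 1e-6), 1)
}

#' Fixed soil background spectrum
#'
#' A dull substrate whose reflectance rises gently with wavelength (darker in
#' the blue), giving a low NDVI so background pixels fall outside the plant
#' masks.
#'
#' @param wavelengths wavelengths in nm.
#' @return Reflectance vector in `(0, 1]`.
#' @export
soil_reflectance <- function(wavelengths) {
  wl <- as.numeric(wavelengths)
  pmin(pmax(0.06 + 0.36 * (wl - 400) / 600, 1e-6), 1)
}

#' Render a reflectance spectrum to an 8-bit RGB triple
#'
#' The colour camera is modelled with boxcar bands: R, G and B are the mean
#' reflectance over 600-700, 500-600 and 400-500 nm respectively, scaled to
#' 0-255 and rounded half-up, so a flat unit spectrum (the white standard)
#' maps to (255, 255, 255).
#'
#' @param spectrum reflectance values in `[0, 1]`.
#' @param wavelengths matching wavelengths in nm; every 100-nm band must
#'   contain at least one sample.
#' @return Integer vector `c(R, G, B)` in `[0, 255]`.
#' @export
render_rgb <- function(spectrum, wavelengths) {
  sel <- .rgb_band_sets(wavelengths)
  vals <- vapply(sel, function(idx) mean(spectrum[idx]), numeric(1))
  as.integer(pmin(pmax(floor(vals * 255 + 0.5), 0), 255))
}

# band membership for the three boxcar channels, with coverage check
.rgb_band_sets <- function(wavelengths) {
  bands <- list(R = c(600, 700), G = c(500, 600), B = c(400, 500))
  sel <- lapply(bands, function(b) {
    which(wavelengths >= b[1] & wavelengths <= b[2])
  })
  empty <- vapply(sel, length, integer(1)) == 0
  if (any(empty)) {
    stop("spectral coverage gap: no samples in the ",
         paste(names(sel)[empty], collapse = ", "),
         " band(s); spectrum must cover 400-700 nm")
  }
  sel
}

#' Scene layout
#'
#' Geometry of one rendered pallet image: overall raster size, the white
#' reflectance standard patch (top-right strip), the plant region below it,
#' and the per-ROI elliptical plant blobs.
#'
#' @param height,width raster size in pixels.
#' @param white_rows number of top rows reserved for the white-standard strip.
#' @param n_rois number of regions of interest (default 10, arranged 2 x 5).
#' @param blob_fraction fraction of each ROI's half-extent used as ellipse
#'   semi-axes (default 0.62, giving roughly 30% plant pixels per scene).
#' @return A named list of class `"scene_layout"`.
#' @export
scene_layout <- function(height = 36, width = 90, white_rows = 6,
                         n_rois = 10, blob_fraction = 0.62) {
  if (height <= white_rows || width < 10 || height < 10) {
    stop("scene dimensions too small for the layout")
  }
  white_patch <- rect(0, white_rows, width - min(width %/% 4, 30), width)
  plant_region <- rect(white_rows, height, 0, width)
  structure(list(height = as.integer(height), width = as.integer(width),
                 white_patch = white_patch, plant_region = plant_region,
                 n_rois = n_rois, blob_fraction = blob_fraction),
            class = "scene_layout")
}

# Deterministic truth mask: one centred ellipse of plant pixels per ROI.
.truth_mask <- function(layout) {
  m <- matrix(FALSE, layout$height, layout$width)
  rois <- default_rois(c(layout$height, layout$width), n = layout$n_rois,
                       region = layout$plant_region)
  for (i in seq_len(nrow(rois))) {
    r0 <- rois$r0[i]; r1 <- rois$r1[i]; c0 <- rois$c0[i]; c1 <- rois$c1[i]
    cy <- (r0 + r1 - 1) / 2; cx <- (c0 + c1 - 1) / 2
    ay <- layout$blob_fraction * (r1 - r0) / 2
    ax <- layout$blob_fraction * (c1 - c0) / 2
    rows <- r0:(r1 - 1); cols <- c0:(c1 - 1)
    d <- outer(((rows - cy) / ay)^2, ((cols - cx) / ax)^2, `+`)
    m[rows + 1, cols + 1] <- m[rows + 1, cols + 1] | (d <= 1)
  }
  m
}

#' Render one synthetic scene
#'
#' Produces a co-registered bundle for one (scenario, day): an 8-bit RGB
#' image, a reflectance cube over a wavelength grid, dark and maximal
#' fluorescence maps, the ground-truth plant mask and the white-standard
#' rectangle. Plant pixels carry [leaf_reflectance()] spectra for the
#' scenario's pigment state with per-pixel state jitter and multiplicative
#' noise; background carries the fixed [soil_reflectance()] spectrum; the
#' white patch is flat reflectance 1. Fluorescence maps satisfy
#' `(Fm - F0)/Fm = ceiling * vitality` exactly when `state_jitter_sd = 0`.
#'
#' @param scenario a [stress_scenario()].
#' @param day measurement day.
#' @param layout a [scene_layout()].
#' @param seed base integer seed; the draw is a deterministic function of
#'   (scenario, day, seed), independent of rendering order.
#' @param wavelengths cube wavelength grid (default 204 bands over
#'   400-1000 nm).
#' @param opts renderer options from [render_options()].
#' @return A list of class `"scene_bundle"` with elements `rgb` (HxWx3
#'   integer array), `cube` (HxWxB reflectance array), `wavelengths`,
#'   `f0_map`, `fm_map`, `truth_mask`, `white_patch`, `layout` and `meta`.
#' @export
render_scene <- function(scenario, day, layout = scene_layout(), seed = 1,
                         wavelengths = seq(400, 1000, length.out = 204),
                         opts = render_options()) {
  stopifnot(inherits(scenario, "stress_scenario"),
            inherits(layout, "scene_layout"))
  if (layout$height <= 0 || layout$width <= 0) {
    stop("non-positive image dimensions")
  }
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing")
  }
  state <- stress_trajectory(scenario, day)
  H <- layout$height; W <- layout$width; B <- length(wavelengths)
  mask <- .truth_mask(layout)
  n_plant <- sum(mask)

  sseed <- scene_seed(seed, scenario$species, scenario$treatment, day)
  cube <- array(0, dim = c(H, W, B))
  soil <- soil_reflectance(wavelengths)
  for (b in seq_len(B)) cube[, , b] <- soil[b]

  f0 <- matrix(0, H, W)
  fm <- matrix(0, H, W)

  with_seed(sseed, {
    sj <- opts$state_jitter_sd
    jit <- function(n) {
      if (sj > 0) exp(rnorm(n, -sj^2 / 2, sj)) else rep(1, n)
    }
    chl_px <- pmin(pmax(state$chl * jit(n_plant), 0), 1)
    car_px <- pmin(pmax(state$car * jit(n_plant), 0), 1)
    vit_px <- pmin(pmax(state$vitality * jit(n_plant), 0), 1)
    ns <- opts$noise_sd
    gain_px <- if (ns > 0) exp(rnorm(n_plant, -ns^2 / 2, ns)) else rep(1, n_plant)

    # spectra for all plant pixels at once: B x n matrix
    base <- leaf_reflectance(pigment_state(1, 1, 1), wavelengths, opts)
    # recompute attenuation components once, then scale per pixel
    wl <- as.numeric(wavelengths)
    s680 <- ifelse(wl <= 680, opts$sigma_680_left, opts$sigma_680_right)
    chl_prof <- opts$chl_well_680 * exp(-(wl - 680)^2 / (2 * s680^2)) +
                opts$chl_well_430 * exp(-(wl - 430)^2 / (2 * opts$sigma_430^2))
    car_prof <- opts$car_well_470 * exp(-(wl - 470)^2 / (2 * opts$sigma_470^2))
    base0 <- opts$vis_base + (opts$nir_plateau - opts$vis_base) /
      (1 + exp(-(wl - opts$red_edge) / opts$red_edge_width))
    spectra <- base0 * exp(-(outer(chl_prof, chl_px) + outer(car_prof, car_px)))
    spectra <- sweep(spectra, 2, gain_px, `*`)
    spectra <- pmin(pmax(spectra, 1e-6), 1)

    idx <- which(mask)  # column-major pixel indices into H x W planes
    for (b in seq_len(B)) {
      plane <- cube[, , b]
      plane[idx] <- spectra[b, ]
      cube[, , b] <- plane
    }

    fm_px <- 1000 * (if (ns > 0) exp(rnorm(n_plant, -ns^2 / 2, ns)) else 1)
    fvfm_px <- pmin(pmax(opts$fvfm_ceiling * vit_px, 0), 1)
    fm[idx] <- fm_px
    f0[idx] <- fm_px * (1 - fvfm_px)
  })

  # white standard: flat reflectance 1, no noise
  wp <- layout$white_patch
  for (b in seq_len(B)) {
    plane <- cube[, , b]
    plane[rect_rows(wp), rect_cols(wp)] <- 1
    cube[, , b] <- plane
  }

  # RGB from the (noisy) cube via the boxcar camera model
  sel <- .rgb_band_sets(wavelengths)
  rgb <- array(0L, dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- apply(cube[, , sel[[ch]], drop = FALSE], c(1, 2), mean)
    rgb[, , ch] <- matrix(as.integer(pmin(pmax(floor(plane * 255 + 0.5), 0), 255)),
                          H, W)
  }

  structure(list(
    rgb = rgb, cube = cube, wavelengths = as.numeric(wavelengths),
    f0_map = f0, fm_map = fm, truth_mask = mask, white_patch = wp,
    layout = layout,
    meta = list(species = scenario$species, treatment = scenario$treatment,
                day = day, onset = scenario$onset, seed = seed,
                scene_seed = sseed, state = state)
  ), class = "scene_bundle")
}

#' @export
print.scene_bundle <- function(x, ...) {
  cat(sprintf(
    "<scene_bundle> %s / %s day %g: %dx%d px, %d bands, %.1f%% plant pixels\n",
    x$meta$species, x$meta$treatment, x$meta$day,
    dim(x$rgb)[1], dim(x$rgb)[2], length(x$wavelengths),
    100 * mean(x$truth_mask)))
  invisible(x)
}

#' Default experiment configuration
#'
#' The emulated study design: two species, five treatments (control, drought,
#' NaCl at 100/200/400 mM), six measurement days and 10 ROIs per scene.
#'
#' @param species,treatments,days design factors.
#' @param layout a [scene_layout()].
#' @param opts renderer options.
#' @return A named list.
#' @export
experiment_config <- function(species = c("pea", "wheat"),
                              treatments = c("control", "drought", "nacl100",
                                             "nacl200", "nacl400"),
                              days = c(1, 3, 5, 8, 10, 12),
                              layout = scene_layout(),
                              opts = render_options()) {
  if (length(treatments) == 0) stop("treatment list must not be empty")
  if (length(species) == 0) stop("species list must not be empty")
  list(species = species, treatments = treatments, days = days,
       layout = layout, opts = opts)
}

#' Generate a full synthetic experiment
#'
#' One [render_scene()] bundle per (species, treatment, day) cell of the
#' configured design, plus a manifest table recording provenance. The
#' manifest is a deterministic function of the configuration alone, so two
#' runs with different seeds differ only in pixel noise.
#'
#' @param config from [experiment_config()].
#' @param seed base integer seed.
#' @return A list with elements `bundles` (named list of scene bundles) and
#'   `manifest` (data frame).
#' @export
generate_experiment <- function(config = experiment_config(), seed = 1) {
  if (length(config$treatments) == 0) stop("treatment list must not be empty")
  grid <- expand.grid(day = config$days, treatment = config$treatments,
                      species = config$species, stringsAsFactors = FALSE)
  bundles <- vector("list", nrow(grid))
  names(bundles) <- sprintf("%s_%s_d%02d", grid$species, grid$treatment,
                            grid$day)
  for (i in seq_len(nrow(grid))) {
    scen <- stress_scenario(grid$species[i], grid$treatment[i],
                            days = config$days)
    bundles[[i]] <- render_scene(scen, grid$day[i], layout = config$layout,
                                 seed = seed, opts = config$opts)
  }
  manifest <- data.frame(
    scene_id = names(bundles),
    species = grid$species, treatment = grid$treatment, day = grid$day,
    height = config$layout$height, width = config$layout$width,
    bands = length(bundles[[1]]$wavelengths),
    n_rois = config$layout$n_rois,
    plant_fraction = vapply(bundles, function(b) mean(b$truth_mask),
                            numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(bundles = bundles, manifest = manifest)
}
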