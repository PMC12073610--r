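#' RGB plant-mask scores
#'
#' Ratio-based scores used to separate plant from background pixels in colour
#' images of pea and wheat pallets. For channel intensities R, G, B the
#' scores are
#'
#' pea:   `5 * 255 * (0.1 G) / (0.1 G + 0.1 R + B)`
#'
#' wheat: `5 * 255 * (0.1 G - R) / (0.1 G + 0.1 R + B)`
#'
#' A pixel is "plant" when its score falls strictly inside the species
#' window: (115.33, 139.3) for pea and (36.39, 140) for wheat. Both scores
#' are invariant to rescaling all three channels by a common positive factor,
#' so raw 8-bit and white-normalized channels give the same classification;
#' raw 8-bit input is the documented convention (the 5*255 factor implies
#' it). Pixels with a zero denominator (R = G = B = 0) score `NA` and are
#' classified background.
#'
#' The standard windows are narrow: the wheat numerator is positive only when
#' G > 10 R, and the pea window requires B close to 0.8-1.0 G, which excludes
#' most green-foliage colours. They are implemented exactly in this conventional form;
#' `window` and the `ndvi_plant_mask()` alternative are provided for
#' sensitivity analysis.
#'
#' @param R,G,B non-negative channel intensities (scalars, vectors or
#'   matrices of equal shape).
#' @param window length-2 numeric, the open score interval classed as plant.
#' @return `mask_score_*()` return the numeric score; `mask_*()` return a
#'   logical plant indicator of the same shape.
#' @export
mask_score_pea <- function(R, G, B) {
  den <- 0.1 * G + 0.1 * R + B
  score <- 5 * 255 * (0.1 * G) / den
  score[den == 0] <- NA_real_
  score
}

#' @rdname mask_score_pea
#' @export
mask_score_wheat <- function(R, G, B) {
  den <- 0.1 * G + 0.1 * R + B
  score <- 5 * 255 * (0.1 * G - R) / den
  score[den == 0] <- NA_real_
  score
}

#' @rdname mask_score_pea
#' @export
mask_pea <- function(R, G, B, window = c(115.33, 139.3)) {
  s <- mask_score_pea(R, G, B)
  out <- !is.na(s) & s > window[1] & s < window[2]
  if (anyNA(s)) {
    message(sum(is.na(s)), " zero-denominator pixel(s) classified background")
  }
  out
}

#' @rdname mask_score_pea
#' @export
mask_wheat <- function(R, G, B, window = c(36.39, 140)) {
  s <- mask_score_wheat(R, G, B)
  out <- !is.na(s) & s > window[1] & s < window[2]
  if (anyNA(s)) {
    message(sum(is.na(s)), " zero-denominator pixel(s) classified background")
  }
  out
}

#' RGB plant mask for a species
#'
#' Applies the species score ([mask_score_pea()] or [mask_score_wheat()]) to
#' an `H x W x 3` 8-bit image.
#'
#' @param img `H x W x 3` array of 8-bit intensities.
#' @param species `"pea"` or `"wheat"`.
#' @param window optional score window override.
#' @return An `H x W` logical matrix of class `"plant_mask"` with a
#'   `provenance` attribute.
#' @export
rgb_plant_mask <- function(img, species = c("pea", "wheat"), window = NULL) {
  species <- match.arg(species)
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop("img must be an H x W x 3 array")
  }
  R <- img[, , 1]; G <- img[, , 2]; B <- img[, , 3]
  m <- if (species == "pea") {
    if (is.null(window)) mask_pea(R, G, B) else mask_pea(R, G, B, window)
  } else {
    if (is.null(window)) mask_wheat(R, G, B) else mask_wheat(R, G, B, window)
  }
  structure(m, class = c("plant_mask", class(m)),
            provenance = paste0("rgb_mask_", species))
}

#' NDVI-threshold plant mask
#'
#' Classifies a pixel as plant when its NDVI strictly exceeds the species
#' threshold: 0.5 for pea, 0.4 for wheat. An all-background map is returned
#' without error.
#'
#' @param ndvi_map `H x W` numeric matrix with values in `[-1, 1]` (`NA`
#'   allowed; treated as background).
#' @param species `"pea"` or `"wheat"`.
#' @return An `H x W` logical matrix of class `"plant_mask"`.
#' @export
ndvi_plant_mask <- function(ndvi_map, species = c("pea", "wheat")) {
  species <- match.arg(species)
  rng <- range(ndvi_map, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9)) {
    stop("NDVI map has values outside [-1, 1]")
  }
  thr <- c(pea = 0.5, wheat = 0.4)[[species]]
  m <- !is.na(ndvi_map) & ndvi_map > thr
  structure(m, class = c("plant_mask", class(m)), provenance = "ndvi_threshold")
}

#' Default grid of rectangular regions of interest
#'
#' A deterministic grid of `n` equal, pairwise-disjoint rectangles covering
#' the given region (default: the whole raster). With the default `n = 10`
#' the grid is 2 rows by 5 columns. Pass `region` to exclude the
#' white-standard strip; a user-supplied ROI table (see [read_rois()])
#' overrides the default everywhere it is accepted.
#'
#' @param shape `c(height, width)` of the raster.
#' @param n number of ROIs (default 10).
#' @param region optional [rect()] to subdivide instead of the full raster.
#' @return A data frame of class `"roi_set"` with columns `label`, `r0`,
#'   `r1`, `c0`, `c1` (0-based, half-open).
#' @export
default_rois <- function(shape, n = 10, region = NULL) {
  if (n < 1) stop("n must be >= 1")
  H <- shape[1]; W <- shape[2]
  if (is.null(region)) region <- rect(0, H, 0, W)
  rect_check_bounds(region, H, W)
  rh <- region[[2]] - region[[1]]; rw <- region[[4]] - region[[3]]
  # grid dimensions: the divisor pair of n closest to the region aspect
  divs <- which(n %% seq_len(n) == 0)
  nr <- divs[which.min(abs(divs / (n / divs) - rh / rw))]
  nc <- n / nr
  if (rh < nr || rw < nc) {
    stop(sprintf("raster region %dx%d too small for a %dx%d ROI grid",
                 rh, rw, nr, nc))
  }
  ch <- rh %/% nr; cw <- rw %/% nc
  out <- expand.grid(gc = seq_len(nc) - 1L, gr = seq_len(nr) - 1L)
  rois <- data.frame(
    label = sprintf("roi%02d", seq_len(n)),
    r0 = region[[1]] + out$gr * ch,
    r1 = region[[1]] + (out$gr + 1L) * ch,
    c0 = region[[3]] + out$gc * cw,
    c1 = region[[3]] + (out$gc + 1L) * cw,
    stringsAsFactors = FALSE
  )
  structure(rois, class = c("roi_set", "data.frame"))
}

#' Read and write ROI definition tables
#'
#' BED-like CSV with columns `label, r0, r1, c0, c1` in the package's 0-based
#' half-open convention.
#'
#' @param path CSV path.
#' @param rois a `roi_set` data frame.
#' @return `read_rois()` returns a `roi_set`.
#' @export
read_rois <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "r0", "r1", "c0", "c1")
  if (!all(need %in% names(df))) {
    stop("ROI file must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$r1 <= df$r0) || any(df$c1 <= df$c0)) {
    stop("ROI file contains empty rectangles")
  }
  structure(df[need], class = c("roi_set", "data.frame"))
}

#' @rdname read_rois
#' @export
write_rois <- function(rois, path) {
  utils::write.csv(as.data.frame(rois), path, row.names = FALSE)
  invisible(path)
}

#' Average a value map over plant pixels within each ROI
#'
#' Mean of `value_map` over the pixels that are plant under `mask` within
#' each ROI rectangle, excluding `NA` values. An ROI containing no valid
#' plant pixel yields `NA` (with a warning), never zero; downstream
#' statistics drop missing values pairwise.
#'
#' @param value_map `H x W` numeric matrix.
#' @param mask `H x W` logical plant mask (use `matrix(TRUE, H, W)` to
#'   average over whole rectangles).
#' @param rois a `roi_set`.
#' @return Named numeric vector, one mean per ROI.
#' @export
roi_average <- function(value_map, mask, rois) {
  d <- dim(value_map)
  if (!identical(dim(mask), d)) stop("value map and mask shapes differ")
  out <- vapply(seq_len(nrow(rois)), function(i) {
    r <- rect(rois$r0[i], rois$r1[i], rois$c0[i], rois$c1[i])
    rect_check_bounds(r, d[1], d[2])
    vals <- value_map[rect_rows(r), rect_cols(r)]
    keep <- mask[rect_rows(r), rect_cols(r)] & !is.na(vals)
    if (!any(keep)) NA_real_ else mean(vals[keep])
  }, numeric(1))
  names(out) <- rois$label
  if (anyNA(out)) {
    warning(sum(is.na(out)), " ROI(s) with no valid plant pixel: ",
            paste(rois$label[is.na(out)], collapse = ", "), call. = FALSE)
  }
  out
}
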