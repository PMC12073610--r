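#' Normalize RGB channels on the white reflectance standard
#'
#' Divides each channel by the corresponding white-standard mean from
#' [white_stats()], converting camera counts to approximate reflectance
#' (values near 1 on the standard itself). Ratio-based indices (r, g, b,
#' VARI, VEG) are unchanged by normalization when the standard is gray, but
#' normalization is kept as an explicit step because real standards are not
#' perfectly neutral.
#'
#' @param R,G,B channel intensities (any equal shape).
#' @param white length-3 positive vector of white means `(R_w, G_w, B_w)`.
#' @return A list with normalized `R`, `G`, `B`.
#' @export
normalize_channels <- function(R, G, B, white) {
  if (length(white) != 3 || anyNA(white) || any(white <= 0)) {
    stop("white reference must be 3 strictly positive channel means")
  }
  list(R = R / white[1], G = G / white[2], B = B / white[3])
}

#' RGB vegetation indices
#'
#' Computes, element-wise over channels of any equal shape, the six indices:
#' normalized coordinates `r = R/(R+G+B)`, `g`, `b`; excess green
#' `ExG = 2 g - r - b` (equivalently `3 g - 1`); the vegetative index
#' `VEG = G / (R^a * B^(1-a))` with `a = 0.667`; and the visible
#' atmospherically resistant index `VARI = (G - R) / (G + R - B)`.
#'
#' Undefined pixels propagate `NA`: all six where `R + G + B = 0`; VEG where
#' `R = 0` or `B = 0`; VARI where `G + R - B = 0`.
#'
#' @param R,G,B non-negative channel values (raw or white-normalized;
#'   every index is invariant to a common positive rescaling of the three
#'   channels).
#' @param a VEG exponent; the conventional constant 0.667.
#' @return A list of numeric arrays `r`, `g`, `b`, `ExG`, `VEG`, `VARI`,
#'   each shaped like the input.
#' @examples
#' rgb_indices(0.2, 0.5, 0.3)
#' @export
rgb_indices <- function(R, G, B, a = 0.667) {
  if (any(R < 0, na.rm = TRUE) || any(G < 0, na.rm = TRUE) ||
      any(B < 0, na.rm = TRUE)) {
    stop("channel intensities must be non-negative")
  }
  s <- R + G + B
  bad_s <- !is.na(s) & s == 0
  s[bad_s] <- NA_real_
  r <- R / s; g <- G / s; b <- B / s
  ExG <- 2 * g - r - b
  den_veg <- R^a * B^(1 - a)
  VEG <- G / den_veg
  VEG[!is.na(den_veg) & den_veg == 0] <- NA_real_
  den_vari <- G + R - B
  VARI <- (G - R) / den_vari
  VARI[!is.na(den_vari) & den_vari == 0] <- NA_real_
  VARI[bad_s] <- NA_real_
  VEG[bad_s] <- NA_real_
  n_bad <- sum(bad_s) + sum(is.na(VEG) & !bad_s) + sum(is.na(VARI) & !bad_s)
  if (n_bad > 0) {
    message(n_bad, " undefined index value(s) set to NA ",
            "(zero channel sum or denominator)")
  }
  list(r = r, g = g, b = b, ExG = ExG, VEG = VEG, VARI = VARI)
}

#' Find the cube band nearest a target wavelength
#'
#' @param wavelengths strictly increasing wavelength vector (nm).
#' @param target target wavelength (nm).
#' @param tol maximum acceptable distance (default 5 nm; a ~3 nm sampling
#'   grid always has a band within tolerance).
#' @return Integer band index (ties resolve to the lower index).
#' @export
nearest_band <- function(wavelengths, target, tol = 5) {
  if (length(wavelengths) == 0) stop("empty wavelength vector")
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be strictly increasing")
  }
  d <- abs(wavelengths - target)
  idx <- which.min(d)  # which.min takes the first (lower) index on ties
  if (d[idx] > tol) {
    stop(sprintf("no band within %g nm of %g nm (nearest: %g nm)",
                 tol, target, wavelengths[idx]))
  }
  idx
}

# shared normalized-difference map over two cube bands
.nd_map <- function(cube, wavelengths, wl_a, wl_b, tol = 5) {
  if (length(dim(cube)) != 3) stop("cube must be an H x W x B array")
  if (dim(cube)[3] != length(wavelengths)) {
    stop("wavelength vector length does not match band count")
  }
  a <- cube[, , nearest_band(wavelengths, wl_a, tol), drop = FALSE]
  b <- cube[, , nearest_band(wavelengths, wl_b, tol), drop = FALSE]
  dim(a) <- dim(cube)[1:2]
  dim(b) <- dim(cube)[1:2]
  den <- a + b
  out <- (a - b) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' NDVI and PRI maps from a reflectance cube
#'
#' `NDVI = (R780 - R680) / (R780 + R680)` and
#' `PRI = (R531 - R570) / (R531 + R570)`, using the cube band nearest each
#' target wavelength (within `tol` nm). Pixels with a zero denominator are
#' `NA`.
#'
#' @param cube `H x W x B` reflectance array.
#' @param wavelengths length-`B` wavelength vector (nm).
#' @param tol band-matching tolerance in nm.
#' @return `H x W` numeric matrix in `[-1, 1]`.
#' @export
ndvi <- function(cube, wavelengths, tol = 5) {
  .nd_map(cube, wavelengths, 780, 680, tol)
}

#' @rdname ndvi
#' @export
pri <- function(cube, wavelengths, tol = 5) {
  .nd_map(cube, wavelengths, 531, 570, tol)
}

#' Potential quantum yield of photosystem II
#'
#' `Fv/Fm = (Fm - F0) / Fm` from dark-adapted PAM fluorometry: `F0` is the
#' dark fluorescence yield, `Fm` the maximal yield under a saturating pulse.
#' Healthy leaves sit near 0.8. Vectorized; `Fm = 0` yields `NA`, and
#' `F0 > Fm` (an invalid measurement) yields `NA` with a warning.
#'
#' @param f0,fm non-negative fluorescence yields (any equal shape).
#' @return Numeric ratio(s) in `[0, 1]` (or `NA`).
#' @examples
#' fv_fm(200, 1000)  # 0.8
#' @export
fv_fm <- function(f0, fm) {
  if (any(f0 < 0, na.rm = TRUE) || any(fm < 0, na.rm = TRUE)) {
    stop("fluorescence yields must be non-negative")
  }
  out <- (fm - f0) / fm
  out[!is.na(fm) & fm == 0] <- NA_real_
  invalid <- !is.na(f0) & !is.na(fm) & fm > 0 & f0 > fm
  if (any(invalid)) {
    warning(sum(invalid), " measurement(s) with F0 > Fm set to NA",
            call. = FALSE)
    out[invalid] <- NA_real_
  }
  out
}
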