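#' Read and write 8-bit RGB rasters
#'
#' Thin wrappers over the png and tiff packages returning/accepting an
#' `H x W x 3` integer array of 8-bit intensities (0-255). Round-trips are
#' lossless. The format is chosen from the file extension (`.png`, `.tif`,
#' `.tiff`).
#'
#' @param path file path.
#' @param img `H x W x 3` array of integers in `[0, 255]` (a single-channel
#'   `H x W` matrix is also accepted, e.g. for masks).
#' @return `read_rgb()` returns an `H x W x 3` integer array (or `H x W`
#'   matrix for single-channel files).
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext)
  )
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]  # drop alpha
  out <- round(img * 255)
  storage.mode(out) <- "integer"
  out
}

#' @rdname read_rgb
#' @export
write_rgb <- function(img, path) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1))
  if (length(dim(img)) != 3 || !dim(img)[3] %in% c(1, 3)) {
    stop("img must be an H x W x 3 array or H x W matrix")
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 255) {
    stop("img values must be in [0, 255]")
  }
  scaled <- img / 255
  if (dim(scaled)[3] == 1) scaled <- scaled[, , 1]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(scaled, path),
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = 8L),
    stop("unsupported raster format: .", ext)
  )
  invisible(path)
}

#' Write a reflectance cube in ENVI format
#'
#' Writes a plain-text ENVI header (`.hdr`) alongside a flat binary file. The
#' header carries the wavelength list in a `wavelength = { ... }` block.
#' Band-sequential (BSQ) little-endian output; `data_type` 4 is IEEE float32
#' (the default, sufficient for reflectance in `[0,1]`), 5 is float64
#' (lossless for double input).
#'
#' @param cube `H x W x B` numeric array.
#' @param wavelengths length-`B` numeric vector (nm).
#' @param path path of the binary file; the header is written at
#'   `<path>.hdr` (or with the extension replaced if `path` ends in a
#'   conventional `.raw`/`.dat`/`.img`).
#' @param data_type ENVI data type code, 4 (float32) or 5 (float64).
#' @return Invisibly, the binary path.
#' @export
write_cube <- function(cube, wavelengths, path, data_type = 4) {
  d <- dim(cube)
  if (length(d) != 3) stop("cube must be an H x W x B array")
  if (length(wavelengths) != d[3]) {
    stop("wavelength vector length (", length(wavelengths),
         ") does not match band count (", d[3], ")")
  }
  if (!data_type %in% c(4, 5)) stop("data_type must be 4 (float32) or 5 (float64)")
  hdr <- c(
    "ENVI",
    "file type = ENVI Standard",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    paste0("data type = ", data_type),
    "interleave = bsq",
    "byte order = 0",
    paste0("wavelength units = nm"),
    paste0("wavelength = { ",
           paste(format(wavelengths, trim = TRUE, digits = 10),
                 collapse = ", "), " }")
  )
  writeLines(hdr, .hdr_path(path))
  # BSQ: band-major; R arrays are [row, col, band] column-major, so permute
  # to samples-fastest order (col within row within band)
  con <- file(path, "wb")
  on.exit(close(con))
  vals <- as.numeric(aperm(cube, c(2, 1, 3)))
  writeBin(vals, con, size = if (data_type == 4) 4L else 8L,
           endian = "little")
  invisible(path)
}

.hdr_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("raw", "dat", "img", "bsq", "bil", "bip")) {
    sub(paste0("\\.", ext, "$"), ".hdr", path, ignore.case = TRUE)
  } else {
    paste0(path, ".hdr")
  }
}

#' Read an ENVI reflectance cube
#'
#' Parses the `.hdr` text header and the flat binary raster. BSQ, BIL and BIP
#' interleaves and data types 1, 2, 3, 4, 5 and 12 are accepted. The header
#' must carry a `wavelength` list whose length equals the band count.
#'
#' @param path path of the binary file (header found as for [write_cube()]).
#' @return A list with `cube` (`H x W x B` numeric array) and `wavelengths`.
#' @export
read_cube <- function(path) {
  hdr_file <- .hdr_path(path)
  if (!file.exists(hdr_file)) stop("ENVI header not found: ", hdr_file)
  if (!file.exists(path)) stop("ENVI binary not found: ", path)
  h <- .parse_envi_header(hdr_file)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("ENVI header missing field(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(h[["wavelength"]])) {
    stop("ENVI header has no wavelength list; cannot resolve index bands")
  }
  W <- as.integer(h[["samples"]]); H <- as.integer(h[["lines"]])
  B <- as.integer(h[["bands"]])
  wavelengths <- as.numeric(h[["wavelength"]])
  if (length(wavelengths) != B) {
    stop("wavelength list length (", length(wavelengths),
         ") does not match band count (", B, ")")
  }
  dt <- as.integer(h[["data type"]])
  spec <- switch(as.character(dt),
    `1` = list(what = "integer", size = 1, signed = FALSE),
    `2` = list(what = "integer", size = 2, signed = TRUE),
    `3` = list(what = "integer", size = 4, signed = TRUE),
    `4` = list(what = "numeric", size = 4, signed = TRUE),
    `5` = list(what = "numeric", size = 8, signed = TRUE),
    `12` = list(what = "integer", size = 2, signed = FALSE),
    stop("unsupported ENVI data type: ", dt)
  )
  endian <- if (!is.null(h[["byte order"]]) && h[["byte order"]] == "1")
    "big" else "little"
  n <- as.double(H) * W * B
  expected_bytes <- n * spec$size
  actual_bytes <- file.size(path)
  if (actual_bytes != expected_bytes + as.numeric(h[["header offset"]] %||% 0)) {
    stop(sprintf(
      "ENVI binary size mismatch: header implies %d x %d x %d (%s bytes), file has %s bytes",
      H, W, B, format(expected_bytes, scientific = FALSE),
      format(actual_bytes, scientific = FALSE)))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  off <- as.integer(h[["header offset"]] %||% 0)
  if (off > 0) readBin(con, "raw", n = off)
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  vals <- as.numeric(vals)
  inter <- tolower(h[["interleave"]])
  cube <- switch(inter,
    bsq = aperm(array(vals, dim = c(W, H, B)), c(2, 1, 3)),
    bil = aperm(array(vals, dim = c(W, B, H)), c(3, 1, 2)),
    bip = aperm(array(vals, dim = c(B, W, H)), c(3, 2, 1)),
    stop("unsupported interleave: ", inter)
  )
  list(cube = cube, wavelengths = wavelengths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse "key = value" ENVI header lines; { } blocks may span lines.
.parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ENVI") {
    stop("not an ENVI header (missing magic line): ", path)
  }
  lines <- lines[-1]
  # merge continuation lines of unterminated { } blocks
  merged <- character(0)
  buf <- ""
  open <- FALSE
  for (ln in lines) {
    buf <- if (open) paste(buf, ln) else ln
    open <- lengths(regmatches(buf, gregexpr("{", buf, fixed = TRUE))) >
      lengths(regmatches(buf, gregexpr("}", buf, fixed = TRUE)))
    if (!open) {
      merged <- c(merged, buf)
      buf <- ""
    }
  }
  if (open) stop("unterminated { } block in ENVI header")
  out <- list()
  for (line in merged) {
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) next
    key <- tolower(trimws(substr(line, 1, eq - 1)))
    val <- trimws(gsub("[{}]", " ", substr(line, eq + 1, nchar(line))))
    out[[key]] <- if (grepl(",", val)) {
      trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    } else {
      trimws(val)
    }
  }
  out
}

#' White reflectance standard statistics
#'
#' Mean intensity (or reflectance) of each channel/band over the
#' white-standard rectangle. Used to normalize RGB channels before index
#' computation.
#'
#' @param raster `H x W x C` array (RGB image or reflectance cube) or
#'   `H x W` matrix.
#' @param white_patch a [rect()] locating the standard; must be non-empty and
#'   within bounds.
#' @return Numeric vector of per-channel means, all strictly positive.
#' @export
white_stats <- function(raster, white_patch) {
  d <- dim(raster)
  if (is.null(d) || length(d) < 2) stop("raster must be a matrix or array")
  rect_check_bounds(white_patch, d[1], d[2])
  rows <- rect_rows(white_patch); cols <- rect_cols(white_patch)
  if (length(d) == 2) raster <- array(raster, dim = c(d, 1))
  means <- apply(raster[rows, cols, , drop = FALSE], 3, mean)
  if (anyNA(means) || any(means <= 0)) {
    stop("white standard has a non-positive mean channel; ",
         "a saturated-black standard is invalid")
  }
  means
}

#' Write and read a numeric matrix as CSV (fluorescence maps)
#'
#' Plain headerless CSV, one image row per line; round-trips doubles at full
#' precision.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `read_matrix_csv()` returns a numeric matrix.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}
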