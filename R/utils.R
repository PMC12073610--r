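#' Rectangle helpers
#'
#' Rectangles are used throughout the package to locate the white reflectance
#' standard and the regions of interest (ROIs). The convention everywhere is
#' row-major, 0-based, half-open: a rectangle `c(r0, r1, c0, c1)` covers image
#' rows `r0 .. r1 - 1` and columns `c0 .. c1 - 1` (0-based).
#'
#' @param r0,r1,c0,c1 integer bounds, `0 <= r0 < r1`, `0 <= c0 < c1`.
#' @return An integer vector `c(r0, r1, c0, c1)` of class `"rect"`.
#' @export
rect <- function(r0, r1, c0, c1) {
  x <- as.integer(c(r0, r1, c0, c1))
  if (anyNA(x)) stop("rectangle bounds must be finite integers")
  if (x[1] < 0 || x[3] < 0) stop("rectangle bounds must be non-negative")
  if (x[2] <= x[1] || x[4] <= x[3]) {
    stop("empty rectangle: need r0 < r1 and c0 < c1 (half-open convention)")
  }
  structure(x, names = c("r0", "r1", "c0", "c1"), class = "rect")
}

# 1-based row/column index vectors for subsetting R matrices
rect_rows <- function(r) (r[[1]] + 1L):r[[2]]
rect_cols <- function(r) (r[[3]] + 1L):r[[4]]

rect_check_bounds <- function(r, nrow, ncol) {
  if (r[[2]] > nrow || r[[4]] > ncol) {
    stop(sprintf("rectangle [%d,%d)x[%d,%d) exceeds raster extent %dx%d",
                 r[[1]], r[[2]], r[[3]], r[[4]], nrow, ncol))
  }
  invisible(r)
}

rect_area <- function(r) (r[[2]] - r[[1]]) * (r[[4]] - r[[3]])

#' @export
print.rect <- function(x, ...) {
  cat(sprintf("<rect> rows [%d, %d) x cols [%d, %d)\n",
              x[[1]], x[[2]], x[[3]], x[[4]]))
  invisible(x)
}

# Deterministic scene-level seed: a small string hash folded into the base
# seed, so draws depend on scene identity rather than generation order.
scene_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "|")
  h <- 0
  m <- 2147483647  # 2^31 - 1, keeps everything in exact double range
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% m
  as.integer((h + as.double(seed) * 7919) %% m)
}

# Evaluate an expression with a local RNG state (restores the caller's seed).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read and write plain-text key-value configuration files
#'
#' One `key = value` pair per line; blank lines and lines starting with `#`
#' are ignored. Values are stored as strings; comma-separated lists are split
#' on read.
#'
#' @param path file path.
#' @param config named list of scalars or vectors.
#' @return `read_config()` returns a named list of character vectors.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line (no '='): ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    out[[key]] <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  }
  out
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Internal: NaN (from empty means) -> NA
nan_to_na <- function(x) { x[is.nan(x)] <- NA_real_; x }
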