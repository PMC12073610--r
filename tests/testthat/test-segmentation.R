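test_that("mask scores match the scalar oracle and the standard windows", {
  # gray pixel: 1275 * 0.1 / 1.2 = 106.25, below the pea window
  expect_equal(mask_score_pea(100, 100, 100), 106.25)
  expect_false(mask_pea(100, 100, 100))

  # a bluish-green pixel inside the pea window
  expect_equal(mask_score_pea(51, 255, 217),
               ref_mask_score_pea(51, 255, 217))
  expect_equal(mask_score_pea(51, 255, 217), 1275 * 25.5 / 247.6,
               tolerance = 1e-12)
  expect_true(mask_pea(51, 255, 217))

  # gray pixel is strongly negative under the wheat score
  expect_equal(mask_score_wheat(100, 100, 100), -956.25)
  expect_false(mask_wheat(100, 100, 100))

  # wheat numerator needs G > 10 R: 1275 * (25.5 - 12) / 154.7
  expect_equal(mask_score_wheat(12, 255, 128),
               ref_mask_score_wheat(12, 255, 128))
  expect_equal(mask_score_wheat(12, 255, 128), 1275 * 13.5 / 154.7,
               tolerance = 1e-12)
  expect_true(mask_wheat(12, 255, 128))

  # pure green scores exactly 1275 under both, outside both windows
  expect_equal(mask_score_wheat(0, 80, 0), 1275)
  expect_false(mask_wheat(0, 80, 0))
  expect_equal(mask_score_pea(0, 80, 0), 1275)
  expect_false(mask_pea(0, 80, 0))

  # zero denominator -> NA score, background
  expect_true(is.na(mask_score_pea(0, 0, 0)))
  expect_false(suppressMessages(mask_pea(0, 0, 0)))
})

test_that("mask scores are invariant under channel rescaling", {
  set.seed(101)
  for (i in 1:50) {
    px <- runif(3, 0, 255)
    c_ <- runif(1, 0.01, 10)
    expect_equal(mask_score_pea(px[1], px[2], px[3]),
                 mask_score_pea(c_ * px[1], c_ * px[2], c_ * px[3]),
                 tolerance = 1e-12)
    expect_equal(mask_score_wheat(px[1], px[2], px[3]),
                 mask_score_wheat(c_ * px[1], c_ * px[2], c_ * px[3]),
                 tolerance = 1e-12)
  }
})

test_that("rgb_plant_mask recovers constructed in-window plant pixels", {
  # plant colours chosen inside each species window; background is gray
  H <- 12; W <- 12
  for (sp in c("pea", "wheat")) {
    img <- array(120L, dim = c(H, W, 3))
    plant_px <- cbind(rep(3:8, each = 6), rep(3:8, times = 6))
    col <- if (sp == "pea") c(51L, 255L, 217L) else c(12L, 255L, 128L)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[plant_px] <- col[ch]
      img[, , ch] <- plane
    }
    m <- rgb_plant_mask(img, sp)
    truth <- matrix(FALSE, H, W); truth[plant_px] <- TRUE
    expect_gte(sum(m & truth) / sum(truth), 0.9)
    expect_identical(sum(m & !truth), 0L)
    expect_equal(attr(m, "provenance"), paste0("rgb_mask_", sp))
  }
})

test_that("NDVI threshold masking uses strict per-species thresholds", {
  nd <- matrix(c(0.50, 0.501, 0.45, 0.40, -0.2, NA), 2, 3)
  pea <- ndvi_plant_mask(nd, "pea")
  expect_identical(as.vector(pea), c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  wheat <- ndvi_plant_mask(nd, "wheat")
  expect_identical(as.vector(wheat), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))

  # all-background map is fine
  expect_identical(sum(ndvi_plant_mask(matrix(0.1, 3, 3), "pea")), 0L)
  expect_error(ndvi_plant_mask(matrix(1.5, 2, 2), "pea"), "outside")
  expect_error(ndvi_plant_mask(nd, "maize"))
})

test_that("NDVI masks recover >= 90% of truth pixels on rendered scenes", {
  for (sp in c("pea", "wheat")) {
    b <- small_bundle(species = sp, treatment = "control", seed = 3)
    m <- ndvi_plant_mask(ndvi(b$cube, b$wavelengths), sp)
    expect_gte(sum(m & b$truth_mask) / sum(b$truth_mask), 0.9)
    # and rejects soil and the white standard
    expect_lte(sum(m & !b$truth_mask) / sum(!b$truth_mask), 0.05)
  }
})

test_that("default ROI grids tile the region disjointly", {
  rois <- default_rois(c(200, 500), n = 10)
  expect_identical(nrow(rois), 10L)
  expect_true(all(rois$r1 - rois$r0 == 100))
  expect_true(all(rois$c1 - rois$c0 == 100))
  expect_true(all(rois$r1 <= 200 & rois$c1 <= 500))

  # pairwise disjoint, union covers no more than the raster
  area <- sum((rois$r1 - rois$r0) * (rois$c1 - rois$c0))
  expect_lte(area, 200 * 500)
  cells <- matrix(0L, 200, 500)
  for (i in seq_len(nrow(rois))) {
    rr <- (rois$r0[i] + 1):rois$r1[i]; cc <- (rois$c0[i] + 1):rois$c1[i]
    cells[rr, cc] <- cells[rr, cc] + 1L
  }
  expect_lte(max(cells), 1L)

  expect_error(default_rois(c(3, 4), n = 10), "too small")
})

test_that("ROI tables round-trip through CSV", {
  rois <- default_rois(c(40, 100), n = 10)
  p <- withr::local_tempfile(fileext = ".csv")
  write_rois(rois, p)
  back <- read_rois(p)
  expect_equal(as.data.frame(back), as.data.frame(rois))
})

test_that("roi_average masks, averages and propagates missing ROIs", {
  rois <- default_rois(c(4, 10), n = 2)
  const <- matrix(7.5, 4, 10)
  all_mask <- matrix(TRUE, 4, 10)
  expect_equal(unname(roi_average(const, all_mask, rois)), c(7.5, 7.5))

  # off-mask pixels are excluded: checkerboard keeps only the 1s
  vals <- matrix(9, 4, 10)
  cb <- (row(vals) + col(vals)) %% 2 == 0
  vals[cb] <- 1
  expect_equal(unname(roi_average(vals, cb, rois)), c(1, 1))

  # an ROI with no plant pixel yields NA with a warning, not zero
  half <- all_mask; half[, 6:10] <- FALSE
  expect_warning(out <- roi_average(const, half, rois), "no valid plant pixel")
  expect_equal(unname(out), c(7.5, NA))

  expect_error(roi_average(const, matrix(TRUE, 2, 2), rois), "shapes differ")
})
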