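Package: rgbcal
Title: Estimating NDVI, PRI and Fv/Fm from RGB Vegetation Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for proximal sensing of plant stress from colour images.
    Computes the six RGB vegetation indices (normalized r, g, b coordinates,
    excess green ExG, vegetative index VEG, and the visible atmospherically
    resistant index VARI) with white-standard normalization, segments plant
    pixels in RGB images and hyperspectral cubes, averages index values over
    rectangular regions of interest, and calibrates linear regressions that
    estimate narrow-band reflectance indices (NDVI, PRI) and the potential
    quantum yield of photosystem II (Fv/Fm) from RGB indices. Includes a
    synthetic greenhouse-scene generator emulating drought and salinity
    stress time courses in pea and wheat, ENVI cube and PNG/TIFF raster I/O,
    and a seedable simulate-process-calibrate-estimate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
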