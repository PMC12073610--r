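---
title: "Methods: RGB-index calibration of NDVI, PRI and Fv/Fm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RGB-index calibration of NDVI, PRI and Fv/Fm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgbcal)
```

## The measurement model

`rgbcal` treats a stress-phenotyping experiment as a chain of four stages.

**1. Imaging.** Each scene is a pallet of plants photographed twice from the
same stand: an 8-bit colour image and a hyperspectral reflectance cube
(default 400–1000 nm, 204 bands, ~3 nm sampling). A white reflectance
standard sits in every frame. Per-plant dark-adapted fluorescence pairs
(F0, Fm) accompany the images.

**2. Segmentation and averaging.** Plant pixels are separated from soil
either by a species NDVI threshold (pea: NDVI > 0.5, wheat: NDVI > 0.4,
strict inequalities) or by the conventional RGB ratio-score windows
(`mask_score_pea`, `mask_score_wheat`). Ten rectangular ROIs per scene
partition the plant area; every index is averaged over the plant pixels
inside each ROI. An ROI without valid plant pixels propagates `NA` — never
zero — and downstream statistics delete missing values pairwise.

**3. Indices.** RGB channels are first normalized on the white-standard
means (`R' = R / R_w`, etc.). The six RGB indices and two narrow-band
indices are computed per pixel and then averaged ("per-pixel-then-average");
the alternative order (average channels per ROI, then compute indices) is
exposed as `process_bundle(per_pixel = FALSE)` for sensitivity analysis
only, because the averaging order is a genuine degree of freedom in this
kind of protocol and the per-pixel order is the documented default.
Fv/Fm = (Fm − F0)/Fm requires Fm > 0 and F0 ≤ Fm; violations yield `NA`
(with a warning for F0 > Fm).

**4. Statistics and calibration.** Per-(species, treatment, day) cell means
feed three analyses:

- *Per-day t-tests* (pooled-variance Student's t by default; Welch via
  `var.equal = FALSE`) comparing each stressed arm against control, starred
  at p < 0.05 / 0.01 / 0.001. Zero-variance degenerate samples are guarded:
  equal means give t = 0, p = 1; unequal means give p = 0 with a
  `degenerate` flag rather than a division by zero.
- *Correlation tables* per stress set — drought (control + drought arms,
  n = 12 cell means over 6 days) and salinization (control + three NaCl
  arms, n = 24) — flagged against the exact two-tailed cutoff
  `critical_r(n) = t_c / sqrt(t_c² + n − 2)`, which is 0.576 (0.58 at two
  decimals) for n = 12 and 0.404 for n = 24 at α = 0.05. No
  multiple-testing correction is applied, matching the descriptive use of
  these tables.
- *Calibration lines*: ordinary least squares of each target (FvFm, NDVI,
  PRI) on each RGB index, per species, pooling all treatment arms (n = 30
  cell means for the full 5-treatment × 6-day design). Pooling the stressed
  arms is deliberate: control-only data spans too little index range for a
  stable slope. R² (identically the squared Pearson correlation for a
  single regressor) measures accuracy; models under the configurable floor
  (default 0.7) are flagged but kept.

Because ExG = 2g − r − b = 3g − 1 is an affine function of g under chromatic
normalization, g and ExG produce identical correlations and identical R² —
duplicated g/ExG rows in a correlation table are an algebraic necessity, not
an error. The test suite asserts this identity to 1e−12 on 10,000 random
pixels.

## The synthetic scene generator

No imagery ships with the package; `generate_experiment()` renders it. The
generator's job is to reproduce the *structure* of a greenhouse stress
experiment — co-registered modalities, a factorial design, ordered treatment
severities, monotone stress trajectories — with physically plausible optics,
not to imitate any particular instrument.

**Leaf optics.** A leaf spectrum is a visible baseline (0.32) rising through
a sigmoid red edge (centre 715 nm, width 12 nm) to a NIR plateau (0.5),
multiplied by `exp(−A(λ))` where the absorption `A` is a sum of Gaussian
wells: chlorophyll wells at 430 nm (depth 2.2, σ 40 nm) and 680 nm (depth
1.9), and a carotenoid well at 470 nm (depth 1.6, σ 25 nm), each scaled by
the relative pigment content. The 680 nm well is two-sided — σ 60 nm toward
the green, σ 30 nm toward the NIR — so that (i) the red edge stays sharp and
the NIR plateau clean, and (ii) chlorophyll loss raises reflectance at
570 nm more than at 531 nm, making PRI *fall* under stress as observed,
without simulating xanthophyll-cycle kinetics (explicitly out of scope).
A healthy leaf renders at NDVI ≈ 0.82 and PRI ≈ 0.05; soil is a fixed dull
spectrum (NDVI ≈ 0.12) that falls outside every plant mask.

**Stress trajectories.** Three latent states in [0, 1] — chl, car, vitality
— start at 1 and decay exponentially once the treatment's onset day is
reached (drought: day 3; NaCl: day 1, matching the earliest detectable
responses the design emulates). Decay rates are calibrated so day-12
vitality hits fixed endpoints: Fv/Fm (= 0.8 × vitality) reaches ≈ 0.2 for
pea drought, ≈ 0.1 for wheat drought, ≈ 0.25 for pea NaCl 400 mM and
≈ 0.5/0.4/0.3 for wheat NaCl 100/200/400 mM, with 100 and 200 mM only
mildly affecting pea. Severity is ordered NaCl 100 ≤ 200 ≤ 400 ≤ drought by
construction. Chlorophyll decays faster than carotenoids under drought
(factors 0.55 vs 0.35 of the vitality rate) and at equal rates (0.45) under
salinity — the mechanism that makes the blue coordinate respond to salt but
barely to drought. No quantitative pigment measurements exist to calibrate
against, so these rates are fixed once from the qualitative time-course
shapes and not revisited.

**Rendering and noise.** Plant pixels are elliptical blobs centred in each
ROI cell (~30% plant pixels per scene, within the 10–60% acceptance band);
the white patch is flat reflectance 1 (rendering to RGB 255,255,255); RGB
channels are boxcar means of the cube over 600–700/500–600/400–500 nm
scaled to 8 bits with half-up rounding. Two noise sources apply to plant
pixels: lognormal multiplicative reflectance noise (σ = 5%) and lognormal
per-pixel pigment-state jitter (σ = 3%). The jitter exists because every
RGB index and both narrow-band indices are ratios — purely multiplicative
pixel noise cancels exactly, which would leave all ROI means identical and
make the t-test layer degenerate. With jitter, ROI means acquire realistic
within-day variance while `noise_sd = 0, state_jitter_sd = 0` still gives
bit-exact noiseless renders in which Fv/Fm recovers 0.8 × vitality exactly.

**Seeding.** One base seed fans out to per-scene seeds through a string hash
of (species, treatment, day), so draws are invariant to rendering order and
the experiment manifest is a function of the configuration alone.

**What the generator does not emulate.** Radiative transfer (no
PROSPECT/SAIL), canopy geometry, illumination/BRDF effects, instrument
spectral response functions, xanthophyll dynamics, or the two-phasic
non-monotone index trajectories real plants sometimes show under moderate
salt. Passing tests therefore demonstrate that the *pipeline* is correct and
that the calibration machinery recovers relationships that exist in the
data; they do not validate the regression coefficients for any real camera
or cultivar — real deployments must recalibrate per species and instrument.

## Numerical choices

- **VEG exponent** stored exactly as the conventional constant 0.667, not 2/3.
- **Band matching**: nearest band within 5 nm of the target wavelength (780,
  680, 531, 570 nm), ties to the lower index; a coarser grid is an error,
  never a silent approximation.
- **Rounding**: reflectance → 8-bit uses `floor(x·255 + 0.5)` (half-up), so
  a flat 0.5 spectrum renders as 128.
- **Mask windows**: strict inequalities at both ends, mirroring the
  "more than … and less than …" convention; scores are computed on raw
  8-bit channels (the 5·255 factor implies that convention) but are
  scale-invariant, so normalized channels classify identically.
- **Degenerate inputs**: zero channel sums, zero index denominators, empty
  ROIs, Fm = 0 and F0 > Fm all yield `NA` and are logged/warned, never
  silently zeroed; zero-variance t-tests are flagged as degenerate.
- **Rectangles** are 0-based half-open everywhere (`[r0, r1) × [c0, c1)`),
  row-major, including the ROI CSV interchange format.
- **ENVI I/O**: BSQ float32 (type 4) written by default — lossless at stored
  precision, halving disk traffic versus float64, which remains available
  (type 5) when bit-exact round-trips matter; BSQ/BIL/BIP and types
  1/2/3/4/12 are accepted on read. The wavelength list in the header is
  mandatory on read because index computation is meaningless without it.

## Open design points and how they were settled

- **The conventional RGB mask windows.** The wheat score's numerator
  (0.1·G − R) is positive only when G > 10·R, and the pea window requires
  B ≈ 0.8–1.0·G; neither admits typical green-foliage colours, so on
  rendered scenes the RGB masks select nothing. The formulas and windows are
  implemented exactly in that form, with the window bounds exposed as
  arguments; the NDVI-threshold mask is the pipeline default (`mask =
  "ndvi"`), and the ground-truth mask (`mask = "truth"`) is available for
  synthetic scenes. The mask *operations* are verified against a scalar
  oracle and on rasters constructed with in-window colours.
- **Whether the instrument pre-normalizes reflectance** is unknowable from
  the protocol alone, so white normalization is an explicit, skippable step
  (`normalize = FALSE`).
- **ROI placement** is unspecified in the emulated protocol; a deterministic
  2 × 5 grid over the plant region (excluding the white-standard strip) is
  the default and a BED-like CSV overrides it.
- **t-test flavour**: "Student's t-test" is read as pooled-variance; Welch
  is one argument away.

## Problem sizes

The test suite renders scenes at 20 × 50 px (full wavelength grid) for unit
tests and at the default 36 × 90 px for the end-to-end checks; the full
synthetic design is 2 species × 5 treatments × 6 days = 60 scenes, 600 ROI
records, 36 calibration models with n = 30 cell means each. These sizes give
stable statistics (per-ROI means average hundreds of pixels) while keeping
a full pipeline run to seconds on one CPU.

## Known limitations

- Calibration lines are species- and instrument-specific by nature; the
  package ships no universal coefficients, and estimates for other species
  require new calibration data.
- The generator's monotone trajectories cannot exercise recovery dynamics or
  the non-monotone r/VARI excursions seen under moderate salinity.
- The correlation layer assumes one averaged value per (treatment, day)
  cell; unbalanced or missing cells reduce n and widen the significance
  cutoff accordingly.
- ENVI support covers the common flat-binary dialect only (no compressed or
  tiled variants).
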