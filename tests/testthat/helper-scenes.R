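# Shared fixtures: a small scene layout keeps rendering cheap while the
# default 204-band wavelength grid keeps all index bands resolvable.

small_layout <- function() scene_layout(height = 20, width = 50, white_rows = 4)

small_bundle <- function(species = "pea", treatment = "control", day = 1,
                         seed = 42, opts = render_options()) {
  render_scene(stress_scenario(species, treatment), day,
               layout = small_layout(), seed = seed, opts = opts)
}

# scalar brute-force references used as independent oracles
ref_mask_score_pea <- function(R, G, B) {
  den <- 0.1 * G + 0.1 * R + B
  if (den == 0) return(NA_real_)
  5 * 255 * (0.1 * G) / den
}

ref_mask_score_wheat <- function(R, G, B) {
  den <- 0.1 * G + 0.1 * R + B
  if (den == 0) return(NA_real_)
  5 * 255 * (0.1 * G - R) / den
}

ref_rgb_indices <- function(R, G, B, a = 0.667) {
  s <- R + G + B
  if (s == 0) return(rep(NA_real_, 6))
  r <- R / s; g <- G / s; b <- B / s
  c(r = r, g = g, b = b,
    ExG = 2 * g - r - b,
    VEG = if (R == 0 || B == 0) NA_real_ else G / (R^a * B^(1 - a)),
    VARI = if (G + R - B == 0) NA_real_ else (G - R) / (G + R - B))
}

ref_nd <- function(a, b) if (a + b == 0) NA_real_ else (a - b) / (a + b)
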