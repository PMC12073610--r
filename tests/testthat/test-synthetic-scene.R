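test_that("leaf reflectance is bounded, pigment-sensitive and NDVI-plausible", {
  wl <- seq(400, 1000, length.out = 204)
  healthy <- leaf_reflectance(pigment_state(1, 1, 1), wl)
  degraded <- leaf_reflectance(pigment_state(0.3, 1, 1), wl)

  expect_true(all(healthy > 0 & healthy <= 1))
  expect_true(all(degraded > 0 & degraded <= 1))

  # chlorophyll loss raises red reflectance; (chl + car) loss raises blue
  i680 <- nearest_band(wl, 680)
  expect_gt(degraded[i680], healthy[i680])
  i470 <- nearest_band(wl, 470)
  low_pig <- leaf_reflectance(pigment_state(0.5, 0.5, 1), wl)
  expect_gt(low_pig[i470], healthy[i470])

  # NIR plateau near 0.5 beyond the red edge
  expect_true(all(abs(healthy[wl > 780] - 0.5) < 0.05))

  # a healthy canopy renders with NDVI in the expected range
  nd <- ref_nd(healthy[nearest_band(wl, 780)], healthy[nearest_band(wl, 680)])
  expect_gt(nd, 0.6)
  expect_lt(nd, 0.9)

  expect_error(leaf_reflectance(pigment_state(1, 1, 1), c(300, 500)),
               "400")
  expect_error(pigment_state(1.2, 1, 1), "\\[0, 1\\]")
})

test_that("stress trajectories decay monotonically with ordered severity", {
  days <- c(1, 3, 5, 8, 10, 12)
  ctrl <- stress_trajectory(stress_scenario("pea", "control"), 12)
  expect_equal(c(ctrl$chl, ctrl$car, ctrl$vitality), c(1, 1, 1))

  # pea drought endpoint calibrated to Fv/Fm ~ 0.2 with ceiling 0.8
  end <- stress_trajectory(stress_scenario("pea", "drought"), 12)
  expect_equal(0.8 * end$vitality, 0.2, tolerance = 1e-12)

  for (sp in c("pea", "wheat")) {
    traj <- lapply(c("nacl100", "nacl200", "nacl400", "drought"), function(tr) {
      vapply(days, function(d) {
        stress_trajectory(stress_scenario(sp, tr), d)$vitality
      }, numeric(1))
    })
    # monotone decay in day
    for (v in traj) expect_true(all(diff(v) <= 0))
    # severity ordering nacl100 >= nacl200 >= nacl400 at every day
    expect_true(all(traj[[1]] >= traj[[2]]))
    expect_true(all(traj[[2]] >= traj[[3]]))
  }

  # drought degrades chlorophyll faster than carotenoids; NaCl equally
  dr <- stress_trajectory(stress_scenario("pea", "drought"), 12)
  expect_lt(dr$chl, dr$car)
  na <- stress_trajectory(stress_scenario("pea", "nacl400"), 12)
  expect_equal(na$chl, na$car)

  expect_error(stress_trajectory(stress_scenario("pea", "drought"), 7),
               "not a measurement day")
})

test_that("render_rgb applies the boxcar camera model with half-up rounding", {
  wl <- seq(400, 1000, by = 5)
  expect_identical(render_rgb(rep(1, length(wl)), wl), c(255L, 255L, 255L))
  expect_identical(render_rgb(rep(0, length(wl)), wl), c(0L, 0L, 0L))
  # 0.5 * 255 = 127.5 rounds half-up to 128
  expect_identical(render_rgb(rep(0.5, length(wl)), wl), c(128L, 128L, 128L))
  # spectral coverage gap is rejected
  expect_error(render_rgb(rep(1, 21), seq(400, 500, by = 5)), "coverage gap")
})

test_that("rendered scenes are deterministic, physical and self-consistent", {
  b1 <- small_bundle(seed = 9)
  b2 <- small_bundle(seed = 9)
  expect_identical(b1, b2)

  b3 <- small_bundle(seed = 10)
  expect_false(identical(b1$cube, b3$cube))

  expect_true(all(b1$cube >= 0 & b1$cube <= 1))
  expect_true(all(b1$rgb >= 0 & b1$rgb <= 255))
  expect_true(all(b1$fm_map >= b1$f0_map))
  expect_true(all(b1$f0_map >= 0))

  frac <- mean(b1$truth_mask)
  expect_gt(frac, 0.10)
  expect_lt(frac, 0.60)

  # control scene: mean Fv/Fm over plant pixels near the 0.8 ceiling
  fv <- fv_fm(b1$f0_map, b1$fm_map)
  expect_equal(mean(fv[b1$truth_mask]), 0.8, tolerance = 0.02)

  # white patch maps to pure white in the RGB rendering
  wp <- b1$white_patch
  patch <- b1$rgb[(wp[1] + 1):wp[2], (wp[3] + 1):wp[4], ]
  expect_true(all(patch == 255L))

  expect_error(render_scene(stress_scenario("pea", "control"), 1,
                            layout = small_layout(), seed = 1,
                            wavelengths = c(500, 450)),
               "strictly increasing")
})

test_that("noiseless renders recover Fv/Fm = ceiling * vitality exactly", {
  opts <- render_options(noise_sd = 0, state_jitter_sd = 0)
  b <- render_scene(stress_scenario("pea", "drought"), 8,
                    layout = small_layout(), seed = 1, opts = opts)
  v <- stress_trajectory(stress_scenario("pea", "drought"), 8)$vitality
  fv <- fv_fm(b$f0_map, b$fm_map)
  expect_equal(unique(fv[b$truth_mask]), 0.8 * v, tolerance = 1e-12)
})

test_that("generate_experiment covers the design with a seed-invariant manifest", {
  cfg <- experiment_config(species = "pea",
                           treatments = c("control", "drought"),
                           days = c(1, 5), layout = small_layout())
  e1 <- generate_experiment(cfg, seed = 1)
  expect_length(e1$bundles, 4)
  expect_identical(nrow(e1$manifest), 4L)

  e2 <- generate_experiment(cfg, seed = 2)
  expect_identical(e1$manifest, e2$manifest)
  expect_false(identical(e1$bundles[[1]]$cube, e2$bundles[[1]]$cube))

  expect_error(experiment_config(treatments = character(0)), "empty")
})
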