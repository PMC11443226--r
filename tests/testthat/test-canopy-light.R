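test_that("an unobstructed horizontal leaf absorbs its Lambert share", {
  g <- build_leaf_geometry(1, 1, n_facets = 1, base_angle = 0, tip_angle = 0)
  g$leaf <- 1
  res <- intercept(g, zenith_dome(100), optical_props(0.8, 0.15, 0.05),
                   config = dense_projection())
  expect_equal(res$leaves$absorbed_w, 80, tolerance = 0.01)
  expect_equal(res$leaves$absorbed_wm2, 80, tolerance = 0.01)
  expect_equal(res$leaves$ppfd, 2.275 * res$leaves$absorbed_wm2)
})

test_that("a fully occluded leaf under an opaque leaf absorbs nothing", {
  g <- build_leaf_geometry(1, 1, n_facets = 1, base_angle = 0, tip_angle = 0)
  g$leaf <- 1
  g2 <- g; g2$z0 <- g2$z0 + 0.5; g2$leaf <- 2
  res <- intercept(rbind(g, g2), zenith_dome(100), optical_props(1, 0, 0),
                   config = dense_projection())
  expect_equal(res$leaves$absorbed_w[res$leaves$leaf == 2], 100,
               tolerance = 0.01)
  expect_equal(res$leaves$absorbed_w[res$leaves$leaf == 1], 0)
})

test_that("the scene energy audit closes and absorption never exceeds incidence", {
  scene <- random_leaf_scene(20)
  dome <- build_sky_dome(300, cloud = 0.4, sun_elevation = 55)
  res <- intercept(scene, dome, config = light_config(tile = FALSE,
                                                      cell_size = 0.02,
                                                      sample_spacing = 0.01))
  tt <- res$totals
  expect_equal(tt$absorbed_w + tt$reflected_w + tt$escaped_w, tt$incident_w,
               tolerance = 1e-9)
  expect_lte(tt$absorbed_w, tt$incident_w * (1 + 1e-6))
  expect_true(all(res$leaves$absorbed_wm2 >= 0))
  expect_equal(sum(res$leaves$absorbed_w), tt$absorbed_w, tolerance = 1e-9)
})

test_that("adding an occluder above a leaf never increases its absorbed flux", {
  g <- build_leaf_geometry(0.4, 0.004, n_facets = 2, base = c(0.5, 0.5, 0))
  g$leaf <- 1
  dome <- build_sky_dome(300, cloud = 0.4, sun_elevation = 55)
  cfg <- light_config(tile = FALSE, cell_size = 0.02, sample_spacing = 0.01)
  alone <- intercept(g, dome, config = cfg)$leaves$absorbed_w[1]
  above <- build_leaf_geometry(0.5, 0.006, n_facets = 2,
                               base = c(0.45, 0.45, 0.3))
  above$leaf <- 2
  shaded <- intercept(rbind(g, above), dome, config = cfg)
  expect_lte(shaded$leaves$absorbed_w[shaded$leaves$leaf == 1], alone + 1e-9)
})

test_that("absorbed flux is linear in the dome flux", {
  scene <- random_leaf_scene(10)
  cfg <- light_config(tile = FALSE, cell_size = 0.02, sample_spacing = 0.01)
  d1 <- build_sky_dome(150, 0.4, 55)
  d2 <- build_sky_dome(300, 0.4, 55)
  r1 <- intercept(scene, d1, config = cfg)
  r2 <- intercept(scene, d2, config = cfg)
  expect_equal(r2$leaves$absorbed_wm2, 2 * r1$leaves$absorbed_wm2,
               tolerance = 1e-9)
  expect_equal(leaf_ppfd(r1)$ppfd, 2.275 * r1$leaves$absorbed_wm2)
})

test_that("Monte Carlo and projection modes agree on a random canopy", {
  scene <- random_leaf_scene(20)
  dome <- build_sky_dome(300, cloud = 0.4, sun_elevation = 55)
  proj <- intercept(scene, dome,
                    config = light_config(tile = FALSE, cell_size = 0.02,
                                          sample_spacing = 0.01))
  mc <- intercept(scene, dome,
                  config = light_config(mode = "montecarlo", n_rays = 4e5,
                                        seed = 1, tile = FALSE))
  expect_equal(mc$totals$absorbed_w, proj$totals$absorbed_w, tolerance = 0.03)
  # per-leaf agreement for the better-lit leaves
  big <- proj$leaves$absorbed_w > 0.25 * max(proj$leaves$absorbed_w)
  expect_equal(mc$leaves$absorbed_w[big], proj$leaves$absorbed_w[big],
               tolerance = 0.15)
  # MC is reproducible under a fixed seed
  mc2 <- intercept(scene, dome,
                   config = light_config(mode = "montecarlo", n_rays = 4e5,
                                         seed = 1, tile = FALSE))
  expect_identical(mc$leaves$absorbed_w, mc2$leaves$absorbed_w)
})

test_that("degenerate scenes are rejected", {
  g <- build_leaf_geometry(0.4, 0.004)
  g$leaf <- 1
  expect_error(intercept(g[0, ], zenith_dome(100)), "no facet area")
  expect_error(intercept(g, zenith_dome(100),
                         config = light_config(tile = TRUE)), "tile_size")
  expect_error(light_config(n_rays = 0), "n_rays")
})
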