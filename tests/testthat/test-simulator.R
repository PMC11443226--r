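test_that("a daily step is deterministic given state and weather", {
  w <- generate_synthetic_weather(seed = 3)
  cfg <- simulation_config(plot = c(1.7, 0.5))
  st1 <- season_init(5, seed = 3, config = cfg)
  st2 <- season_init(5, seed = 3, config = cfg)
  for (i in 1:5) {
    st1 <- simulate_step(st1, w[i, ])
    st2 <- simulate_step(st2, w[i, ])
  }
  expect_identical(st1$organ, st2$organ)
  expect_identical(st1$pool, st2$pool)
})

test_that("a zero-radiation day yields no assimilation and only reserve drains", {
  # phenology with no organ born yet: the pool changes by the root draw only
  ph <- default_phenology(leaf_birth_start = 120)
  cfg <- simulation_config(plot = c(1.7, 0.5), phenology = ph)
  st <- season_init(5, seed = 1, config = cfg)
  dark <- tibble::tibble(doy = 91L, tmax_c = 15, tmin_c = 15, cloud = 0,
                         rh = 0.5, co2_ppm = 400, wind_ms = 2)
  st2 <- simulate_step(st, dark)
  expect_equal(st2$records$carbon[[1]]$assim_g, rep(0, st$n_plants))
  expect_equal(st2$pool, rep(cfg$initial_pool * 0.85, st$n_plants))
  expect_true(all(st2$organ$dm == 0))
})

test_that("scapes initiate on day 137 under the default schedule", {
  ph <- default_phenology()
  expect_equal(unique(ph$birth_doy[ph$organ == "scape"]), 137)
  w <- generate_synthetic_weather(seed = 1)
  cfg <- simulation_config(plot = c(1.7, 0.5))
  st <- season_init(5, seed = 1, config = cfg)
  sel <- st$organ$kind == "scape"
  for (i in which(w$doy %in% 135:139)) st <- simulate_step(st, w[i, ])
  expect_true(all(st$organ$len[sel] > 0))  # elongation has begun
  st_pre <- season_init(5, seed = 1, config = cfg)
  st_pre <- simulate_step(st_pre, w[w$doy == 136, ])
  expect_true(all(st_pre$organ$len[sel] == 0))
})

test_that("organ biomass is non-decreasing and bounded by its potential", {
  fx <- small_season()
  org <- fx$state$organ
  expect_true(all(org$dm >= 0))
  expect_true(all(org$dm <= org$dm_pot + 1e-9))
  expect_true(all(fx$state$pool >= 0))
})

test_that("the whole-season carbon ledger closes per plant", {
  fx <- small_season()
  led <- hemsim:::season_summarize(fx$state)$carbon
  by_plant <- dplyr::summarise(
    dplyr::group_by(led, plant),
    assim = sum(assim_g), growth = sum(growth_g),
    gresp = sum(growth_resp_g), maint = sum(maint_g), root = sum(root_g),
    pool_end = pool_g[dplyr::n()], .groups = "drop"
  )
  audit <- fx$config$initial_pool + by_plant$assim -
    (by_plant$growth + by_plant$gresp + by_plant$maint + by_plant$root +
       by_plant$pool_end)
  expect_lt(max(abs(audit)), 1e-6)
  # growth equals the total organ biomass laid down
  organ_dm <- sum(fx$state$organ$dm)
  expect_equal(sum(by_plant$growth), organ_dm, tolerance = 1e-9)
})

test_that("season summaries expose the calibrated endpoints", {
  fx <- small_season()
  res <- hemsim:::season_summarize(fx$state)
  s <- res$summary
  expect_equal(s$mean_buds_per_scape, 40)
  expect_equal(s$scape_len_at_215_m, 1.19, tolerance = 1e-9)
  expect_equal(s$n_plants, nrow(res$scene))
  expect_gt(s$yield_t_ha, 0)
  # fresh:dry linearity: doubling the bud factor doubles fresh yield only
  st2 <- fx$state
  st2$config$fresh_factors <- fresh_weight_factors(bud = 20)
  res2 <- hemsim:::season_summarize(st2)
  expect_equal(res2$summary$yield_t_ha, 2 * s$yield_t_ha, tolerance = 1e-9)
  expect_equal(res2$summary$mean_bud_length_m, s$mean_bud_length_m)
})

test_that("zero emergence produces a budless, yieldless stand", {
  cfg <- simulation_config(plot = c(1.7, 0.5), emergence_rate = 0)
  st <- season_init(5, seed = 1, config = cfg)
  w <- generate_synthetic_weather(seed = 1)
  for (i in 1:3) st <- simulate_step(st, w[i, ])
  res <- hemsim:::season_summarize(st)
  expect_equal(res$summary$yield_t_ha, 0)
  expect_equal(nrow(res$buds), 0)
})

test_that("a season replays identically under a fixed seed", {
  w <- generate_synthetic_weather(seed = 8)
  cfg <- simulation_config(plot = c(1.7, 0.5))
  r1 <- simulate_season(5, weather = w[1:25, ], seed = 8, config = cfg)
  r2 <- simulate_season(5, weather = w[1:25, ], seed = 8, config = cfg)
  expect_equal(r1$organs, r2$organs)
  expect_equal(r1$carbon, r2$carbon)
})
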