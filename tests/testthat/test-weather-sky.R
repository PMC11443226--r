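test_that("daily extraterrestrial radiation matches numeric integration of the solar arc", {
  # independent oracle: integrate solar-constant * max(cos z, 0) over the day
  oracle <- function(lat, doy) {
    delta <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
    e0 <- 1 + 0.033 * cos(2 * pi * doy / 365)
    phi <- lat * pi / 180
    f <- function(h) {
      omega <- pi * (h - 12) / 12
      pmax(sin(phi) * sin(delta) + cos(phi) * cos(delta) * cos(omega), 0)
    }
    1367 * e0 * stats::integrate(f, 0, 24, rel.tol = 1e-10)$value / 24
  }
  for (case in list(c(0, 80), c(40.13, 91), c(40.13, 172), c(-30, 200))) {
    expect_equal(extraterrestrial_radiation(case[1], case[2]),
                 oracle(case[1], case[2]), tolerance = 1e-6)
  }
  # equator at equinox: hand-integrable cosine arc, ~ solar constant / pi
  expect_equal(extraterrestrial_radiation(0, 80),
               1367 / pi * (1 + 0.033 * cos(2 * pi * 80 / 365)),
               tolerance = 0.01)
})

test_that("polar night, solstice monotonicity and solstice symmetry hold", {
  expect_equal(extraterrestrial_radiation(90, 355), 0)
  expect_gt(extraterrestrial_radiation(40.13, 172),
            extraterrestrial_radiation(40.13, 91))
  for (k in c(10, 30, 60)) {
    a <- extraterrestrial_radiation(40.13, 172 - k)
    b <- extraterrestrial_radiation(40.13, 172 + k)
    expect_lt(abs(a - b) / a, 0.01)
  }
})

test_that("CSRM reproduces the hand-evaluated transmission and clamps to physical bounds", {
  # ratio = -0.08 + 0.21*sqrt(16) - 0.012*0.4 = 0.7552
  expect_equal(csrm_daily_radiation(30, 14, 0.4, 400), 302.08)
  # zero diurnal range, clear sky: raw ratio -0.08 clamps to 0
  expect_equal(csrm_daily_radiation(20, 20, 0, 400), 0)
  # increasing cloud can only decrease radiation
  h <- csrm_daily_radiation(30, 14, seq(0, 1, 0.1), 400)
  expect_true(all(diff(h) <= 0))
  # never exceeds extraterrestrial
  expect_true(all(csrm_daily_radiation(45, 5, 0, 400) <= 400))
  expect_error(csrm_daily_radiation(10, 20, 0.5, 400), "tmax")
})

test_that("radiation converts to PPFD with the 2.275 umol/J factor", {
  expect_equal(radiation_to_ppfd(1), 2.275)
  expect_equal(radiation_to_ppfd(0), 0)
  expect_equal(radiation_to_ppfd(248.7), 565.7925)
  expect_error(radiation_to_ppfd(-1), "non-negative")
})

test_that("the sky dome has 72 diffuse sources and closes on the total flux", {
  dome <- build_sky_dome(300, cloud = 0.4, sun_elevation = 55)
  expect_equal(sum(dome$source == "diffuse"), 72)
  expect_equal(nrow(dome), 73)
  expect_true(all(dome$weight >= 0))
  expect_lt(abs(sum(dome$weight) - 300) / 300, 1e-9)
  # unit direction vectors
  expect_equal(dome$ux^2 + dome$uy^2 + dome$uz^2, rep(1, 73))
})

test_that("dome limits: zero flux, full overcast, and the diffuse split is monotone in cloud", {
  expect_true(all(build_sky_dome(0, 0.4, 55)$weight == 0))
  overcast <- build_sky_dome(300, 1, 55)
  expect_equal(overcast$weight[overcast$source == "sun"], 0)
  sun_w <- vapply(c(0, 0.3, 0.7, 1), function(cl) {
    d <- build_sky_dome(300, cl, 55)
    d$weight[d$source == "sun"]
  }, numeric(1))
  expect_true(all(diff(sun_w) < 0))
})

test_that("synthetic weather is reproducible and matches the configured climate", {
  w1 <- generate_synthetic_weather(seed = 1)
  w2 <- generate_synthetic_weather(seed = 1)
  expect_identical(w1, w2)
  expect_false(identical(w1, generate_synthetic_weather(seed = 2)))
  expect_equal(nrow(w1), 152)
  expect_true(all(w1$tmax_c >= w1$tmin_c))
  expect_true(all(w1$cloud >= 0 & w1$cloud <= 1))
  # default noisy season: means close to the configured statistics
  expect_lt(abs(mean((w1$tmax_c + w1$tmin_c) / 2) - 19.1), 0.4)
  expect_lt(abs(mean(w1$cloud) - 0.4) / 0.4, 0.02)
  h <- csrm_daily_radiation(w1$tmax_c, w1$tmin_c, w1$cloud,
                            extraterrestrial_radiation(40.13, w1$doy))
  expect_lt(abs(mean(h) - 248.7) / 248.7, 0.02)
})

test_that("noise-free synthetic weather hits the configured means exactly", {
  z <- list(temp = 0, range = 0, cloud = 0, wind = 0, rh = 0)
  w <- generate_synthetic_weather(seed = 1, noise = z)
  expect_equal(mean((w$tmax_c + w$tmin_c) / 2), 19.1, tolerance = 1e-10)
  expect_equal(mean(w$cloud), 0.4, tolerance = 1e-12)
  h <- csrm_daily_radiation(w$tmax_c, w$tmin_c, w$cloud,
                            extraterrestrial_radiation(40.13, w$doy))
  expect_equal(mean(h), 248.7, tolerance = 1e-6)
  expect_error(generate_synthetic_weather(seed = 1, mean_cloud = 1.5), "cloud")
  expect_error(generate_synthetic_weather(seed = 1, mean_radiation = 2000),
               "infeasible")
})

test_that("weather round-trips through the CSV interface", {
  w <- generate_synthetic_weather(seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_weather_csv(w, path)
  w2 <- read_weather_csv(path)
  expect_equal(as.data.frame(w2), as.data.frame(w), tolerance = 1e-12)
})
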