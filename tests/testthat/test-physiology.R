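test_that("FvCB limits: darkness and the CO2 compensation point give -Rd", {
  p <- photosynthesis_params()
  expect_equal(fvcb_assimilation(300, 0, 25, p), -p$rd25)
  # at Ci = Gamma* the gross terms vanish exactly
  expect_equal(fvcb_assimilation(p$gstar25, 1500, 25, p), -p$rd25)
  expect_error(fvcb_assimilation(-10, 100, 25, p), "positive")
  expect_error(fvcb_assimilation(Inf, 100, 25, p), "non-finite")
})

test_that("FvCB matches an independent scalar evaluation of the limitation laws", {
  p <- photosynthesis_params(vcmax25 = 60, jmax25 = 120, rd25 = 0.9,
                             alpha = 0.24, theta = 0.7)
  ci <- 300; ppfd <- 1500; tk <- 298.15
  # one-off oracle written out term by term
  kc <- 404.9; ko <- 278.4; gstar <- 42.75 # 25 C values, no temperature shift
  ii <- 0.24 * ppfd
  j <- (ii + 120 - sqrt((ii + 120)^2 - 4 * 0.7 * ii * 120)) / (2 * 0.7)
  wc <- 60 * ci / (ci + kc * (1 + 210 / ko))
  wj <- j / 4 * ci / (ci + 2 * gstar)
  a_expected <- min(wc, wj) * (1 - gstar / ci) - 0.9
  expect_equal(fvcb_assimilation(ci, ppfd, 25, p), a_expected,
               tolerance = 1e-10)
})

test_that("BWB conductance follows the slope rule and floors at g0", {
  p <- photosynthesis_params(bwb_m = 10, bwb_g0 = 0.01)
  expect_equal(bwb_conductance(10, 0.6, 400, p), 0.16)
  expect_equal(bwb_conductance(-2, 0.6, 400, p), 0.01)
  expect_equal(bwb_conductance(0, 0.6, 400, p), 0.01)
  # doubling Cs halves the variable term
  g1 <- bwb_conductance(10, 0.6, 400, p) - 0.01
  g2 <- bwb_conductance(10, 0.6, 800, p) - 0.01
  expect_equal(g1, 2 * g2)
  expect_error(bwb_conductance(10, 0.6, 0), "positive")
})

test_that("leaf energy balance solves the flux budget", {
  p <- photosynthesis_params()
  # no absorbed shortwave, closed stomata: leaf sits at air temperature
  expect_equal(leaf_energy_balance(0, 20, 5, 1e-6, 0.5, p), 20,
               tolerance = 1e-3)
  # residual audit at the returned temperature
  sigma <- 5.670374e-8; cp <- 29.3; lambda <- 44000; pres <- 101325
  absorbed <- 300; tair <- 25; wind <- 2; gs <- 0.2; rh <- 0.6
  tl <- leaf_energy_balance(absorbed, tair, wind, gs, rh, p)
  gb <- 0.147 * sqrt(wind / p$leaf_width)
  gtw <- 1 / (1 / gs + 1 / gb)
  es <- function(tc) 611.2 * exp(17.62 * tc / (tc + 243.12))
  resid <- absorbed - p$emissivity * sigma * ((tl + 273.15)^4 - (tair + 273.15)^4) -
    cp * gb * (tl - tair) - lambda * gtw * max(es(tl) - rh * es(tair), 0) / pres
  expect_lt(abs(resid), 0.1)
  # monotone in absorbed flux
  tls <- vapply(c(0, 100, 200, 400), function(a) {
    leaf_energy_balance(a, tair, wind, gs, rh, p)
  }, numeric(1))
  expect_true(all(diff(tls) > 0))
  expect_error(leaf_energy_balance(-5, 20, 2, 0.1, 0.5), "non-negative")
})

test_that("the coupled leaf model converges to a verified fixed point", {
  p <- photosynthesis_params()
  st <- coupled_leaf_flux(ppfd = c(0, 100, 400, 800, 1500), tair = 25,
                          rh = 0.6, co2 = 400, wind = 2, p = p)
  expect_true(all(st$converged))
  # dark leaf: A = -Rd (at the slightly evaporatively-cooled leaf
  # temperature), gs = g0
  expect_lt(abs(st$a_net[1] + p$rd25), 0.02)
  expect_equal(st$gs[1], p$bwb_g0)
  # light response is monotone and Ci stays below Ca when assimilating
  expect_true(all(diff(st$a_net) > 0))
  expect_true(all(st$ci[st$a_net > 0] < 400))
  expect_true(all(st$ci > 0))
  # every sub-equation holds at the returned state (relative residual < 1e-4)
  gb <- 0.147 * sqrt(2 / p$leaf_width)
  a_chk <- fvcb_assimilation(st$ci, c(0, 100, 400, 800, 1500), st$t_leaf, p)
  expect_lt(max(abs(a_chk - st$a_net) / pmax(abs(a_chk), 0.1)), 1e-4)
  cs <- 400 - st$a_net * 1.37 / gb
  gs_chk <- bwb_conductance(st$a_net, 0.6, cs, p)
  expect_lt(max(abs(gs_chk - st$gs) / gs_chk), 1e-4)
  ci_chk <- pmin(pmax(400 - st$a_net * (1.6 / st$gs + 1.37 / gb), 1), 400)
  expect_lt(max(abs(ci_chk - st$ci) / ci_chk), 1e-4)
})

test_that("limitation crossover: Rubisco-limited at low Ci, light-limited at low PPFD", {
  p <- photosynthesis_params()
  low_ci <- hemsim:::fvcb_limitations(100, 1500, 25, p)
  expect_lt(low_ci$wc, low_ci$wj)
  low_light <- hemsim:::fvcb_limitations(300, 60, 25, p)
  expect_lt(low_light$wj, low_light$wc)
})
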