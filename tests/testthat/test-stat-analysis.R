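test_that("goodness-of-fit metrics satisfy their defining limits", {
  obs <- c(1, 2.2, 2.8, 4.1, 5)
  m_perfect <- gof_metrics(obs, obs)
  expect_equal(m_perfect$r_squared, 1)
  expect_equal(m_perfect$rmse, 0)
  m_null <- gof_metrics(obs, rep(mean(obs), 5))
  expect_equal(m_null$r_squared, 0)
  expect_error(gof_metrics(rep(1, 5), obs), "zero variance")
  expect_error(gof_metrics(1:2, 1:2), "length")
})

test_that("metrics match a hand-computed five-point case", {
  obs <- c(2, 4, 5, 4, 6)
  pred <- c(1.8, 3.5, 5.2, 4.5, 5.8)
  m <- gof_metrics(obs, pred)
  # hand arithmetic with the standard definitions
  sse <- sum((obs - pred)^2)              # 0.62
  sst <- sum((obs - mean(obs))^2)         # 8.8
  expect_equal(m$r_squared, 1 - sse / sst)
  expect_equal(m$rmse, sqrt(sse / 5))
  b <- stats::cov(obs, pred) / stats::var(pred)
  a <- mean(obs) - b * mean(pred)
  fit <- a + b * pred
  f_hand <- sum((fit - mean(obs))^2) / (sum((obs - fit)^2) / 3)
  expect_equal(m$f_value, f_hand)
  expect_equal(m$p_value, stats::pf(f_hand, 1, 3, lower.tail = FALSE))
})

test_that("beta calibration recovers known parameters from clean series", {
  truth <- list(w_max = 0.8, t0 = 100, t_m = 125, t_e = 150)
  clean <- simulate_organ_series(truth$w_max, truth$t0, truth$t_m, truth$t_e,
                                 noise_sd = 0, seed = 1)
  fit <- fit_beta(clean, t0 = truth$t0)
  expect_lt(abs(fit$params$t_m - truth$t_m), 0.5)
  expect_lt(abs(fit$params$t_e - truth$t_e), 0.5)
  expect_lt(abs(fit$params$w_max - truth$w_max) / truth$w_max, 0.001)
  expect_gt(fit$metrics$r_squared, 0.999)
})

test_that("beta calibration tolerates field-scale noise over 48 measurements", {
  truth <- list(w_max = 1.19, t0 = 95, t_m = 150, t_e = 200)
  days <- seq(95, 236, by = 3) # 48 sampling dates every 3 days
  ok_r2 <- numeric(0)
  for (seed in 1:5) {
    noisy <- simulate_organ_series(truth$w_max, truth$t0, truth$t_m,
                                   truth$t_e, days = days,
                                   noise_sd = 0.02, seed = seed)
    expect_equal(nrow(noisy), 48)
    fit <- fit_beta(noisy, t0 = truth$t0)
    expect_lt(abs(fit$params$w_max - truth$w_max) / truth$w_max, 0.05)
    expect_lt(abs(fit$params$t_m - truth$t_m) / truth$t_m, 0.05)
    expect_lt(abs(fit$params$t_e - truth$t_e) / truth$t_e, 0.05)
    expect_gt(fit$metrics$r_squared, 0.95)
    ok_r2 <- c(ok_r2, fit$metrics$r_squared)
  }
  # the fit quality sits in the plausible field-calibration band
  expect_true(all(ok_r2 > 0.88 & ok_r2 <= 1))
  expect_error(fit_beta(tibble::tibble(day = 1:6, value = rep(2, 6))),
               "degenerate")
})

test_that("tidy and glance methods expose the beta fit", {
  clean <- simulate_organ_series(0.5, 100, 120, 140, noise_sd = 0, seed = 2)
  fit <- fit_beta(clean, t0 = 100)
  td <- tidy(fit)
  expect_setequal(td$term, c("w_max", "t_m", "t_e", "t0", "c_m"))
  expect_true(all(c("r_squared", "rmse", "f_value") %in% names(glance(fit))))
})

# generative PLS oracle: a 3-construct chain X -> M -> Y with known paths
chain_data <- function(n = 500, seed = 1, b1 = 0.6, b2 = 0.5) {
  set.seed(seed)
  x <- stats::rnorm(n)
  m <- b1 * x + stats::rnorm(n, sd = sqrt(1 - b1^2))
  y <- b2 * m + stats::rnorm(n, sd = sqrt(1 - b2^2))
  lam <- 0.98
  tibble::tibble(
    x1 = x,
    m1 = lam * m + stats::rnorm(n, sd = sqrt(1 - lam^2)),
    m2 = lam * m + stats::rnorm(n, sd = sqrt(1 - lam^2)),
    m3 = lam * m + stats::rnorm(n, sd = sqrt(1 - lam^2)),
    y1 = y
  )
}

chain_spec <- function() {
  plspm_spec(
    blocks = list(X = "x1", M = c("m1", "m2", "m3"), Y = "y1"),
    paths = data.frame(from = c("X", "M"), to = c("M", "Y"))
  )
}

test_that("PLS-PM recovers a known linear chain", {
  fit <- fit_plspm(chain_data(500, seed = 1), chain_spec())
  expect_true(fit$converged)
  p_xm <- fit$paths$estimate[fit$paths$from == "X"]
  p_my <- fit$paths$estimate[fit$paths$from == "M"]
  expect_lt(abs(p_xm - 0.6), 0.05)
  expect_lt(abs(p_my - 0.5), 0.05)
  ind <- fit$indirect
  expect_equal(nrow(ind), 1)
  expect_lt(abs(ind$estimate - 0.30), 0.05)
  # chain product identity holds exactly
  expect_equal(ind$estimate, p_xm * p_my, tolerance = 1e-10)
})

test_that("single-indicator constructs have unit reliability, correlated pairs unit alpha", {
  fit <- fit_plspm(chain_data(200, seed = 2), chain_spec())
  rel <- fit$reliability
  for (cn in c("X", "Y")) {
    row <- rel[rel$construct == cn, ]
    expect_equal(c(row$alpha, row$rho_a, row$rho_c, row$ave), rep(1, 4))
  }
  expect_gt(rel$alpha[rel$construct == "M"], 0.7)
  expect_gt(rel$ave[rel$construct == "M"], 0.5)
  # two perfectly correlated indicators: Cronbach's alpha is exactly 1
  d <- chain_data(100, seed = 3)
  d$m2 <- d$m1
  sp <- plspm_spec(blocks = list(X = "x1", M = c("m1", "m2"), Y = "y1"),
                   paths = data.frame(from = c("X", "M"), to = c("M", "Y")))
  fit2 <- fit_plspm(d, sp)
  expect_equal(fit2$reliability$alpha[fit2$reliability$construct == "M"], 1)
})

test_that("the specification is validated", {
  expect_error(plspm_spec(list(A = "a", B = "a"),
                          data.frame(from = "A", to = "B")), "exactly one")
  expect_error(plspm_spec(list(A = "a", B = "b"),
                          data.frame(from = "A", to = "C")), "unknown")
  expect_error(plspm_spec(list(A = "a", B = "b"),
                          data.frame(from = c("A", "B"), to = c("B", "A"))),
               "acyclic")
  expect_error(fit_plspm(chain_data(5), chain_spec()), "at least 10")
  fit <- fit_plspm(chain_data(100, seed = 4), chain_spec())
  expect_error(indirect_effects(fit, chains = list(c("Y", "X"))), "absent")
})

test_that("indirect effects multiply along declared chains", {
  fit <- fit_plspm(chain_data(120, seed = 5), chain_spec())
  manual <- prod(fit$paths$estimate)
  expect_equal(indirect_effects(fit, chains = list(c("X", "M", "Y")))$estimate,
               manual, tolerance = 1e-12)
  # a zeroed path forces a zero chain product
  fit0 <- fit
  fit0$paths$estimate[1] <- 0
  expect_equal(indirect_effects(fit0)$estimate, 0)
})
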