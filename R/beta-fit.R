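#' Goodness-of-fit metrics
#'
#' Coefficient of determination, root mean squared error and the regression
#' F statistic (1 and n-2 degrees of freedom) of observed against predicted
#' values.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 3).
#' @return A tibble with `r_squared`, `rmse`, `f_value`, `p_value` and `n`.
#' @export
gof_metrics <- function(observed, predicted) {
  n <- length(observed)
  if (length(predicted) != n || n < 3) {
    stop("`observed` and `predicted` must have equal length >= 3", call. = FALSE)
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed values have zero variance", call. = FALSE)
  sse <- sum((observed - predicted)^2)
  r2 <- 1 - sse / sst
  # regression F of observed ~ predicted
  b <- stats::cov(observed, predicted) / stats::var(predicted)
  a <- mean(observed) - b * mean(predicted)
  fitted <- a + b * predicted
  ssreg <- sum((fitted - mean(observed))^2)
  ssres <- sum((observed - fitted)^2)
  f <- (ssreg / 1) / (ssres / (n - 2))
  tibble::tibble(
    r_squared = r2,
    rmse = sqrt(mean((observed - predicted)^2)),
    f_value = f,
    p_value = stats::pf(f, 1, n - 2, lower.tail = FALSE),
    n = n
  )
}

#' Fit the beta growth function to an organ time series
#'
#' Nonlinear least squares of the cumulative beta growth curve to measured
#' organ sizes: estimates the final size `w_max`, the day of maximum growth
#' `t_m` and the day growth ceases `t_e` (organ birth `t0` is taken from the
#' data or supplied). Used to calibrate per-organ growth parameters from
#' repeated field measurements.
#'
#' @param data A data frame with columns `day` and `value` (length in m or
#'   mass in g), at least 5 points spanning the growth period.
#' @param t0 Organ birth day; defaults to the first observation day.
#' @return An object of class `hemsim_beta_fit` with elements `params`
#'   (w_max, t_m, t_e, t0 and the implied peak rate c_m), `metrics`
#'   (from [gof_metrics()]), `fitted`, and the underlying `nls` object.
#'   Supports [tidy()] and [glance()].
#' @export
fit_beta <- function(data, t0 = NULL) {
  stopifnot(all(c("day", "value") %in% names(data)))
  data <- data[order(data$day), ]
  if (nrow(data) < 5) stop("need at least 5 observations", call. = FALSE)
  if (stats::sd(data$value) == 0) {
    stop("degenerate (constant) series cannot be fitted", call. = FALSE)
  }
  if (any(data$value < 0)) stop("organ sizes must be non-negative", call. = FALSE)
  if (is.null(t0)) t0 <- min(data$day)
  day <- data$day
  value <- data$value
  w0 <- max(value)
  te0 <- day[which(value >= 0.97 * w0)[1]]
  slopes <- diff(value) / diff(day)
  tm0 <- day[which.max(slopes)]
  tm0 <- min(max(tm0, t0 + 2), te0 - 2)
  te0 <- max(te0, tm0 + 4)

  fit <- minpack.lm::nlsLM(
    value ~ beta_growth_cumulative(day, t0, tm, te,
                                   beta_cm_for_wmax(wmax, t0, tm, te)),
    start = list(wmax = w0, tm = tm0, te = te0),
    lower = c(wmax = 1e-9, tm = t0 + 1, te = t0 + 3),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  if (cf[["tm"]] >= cf[["te"]]) {
    stop("beta fit collapsed (t_m >= t_e)", call. = FALSE)
  }
  pred <- stats::predict(fit)
  out <- list(
    params = tibble::tibble(
      w_max = cf[["wmax"]], t_m = cf[["tm"]], t_e = cf[["te"]], t0 = t0,
      c_m = beta_cm_for_wmax(cf[["wmax"]], t0, cf[["tm"]], cf[["te"]])
    ),
    metrics = gof_metrics(value, pred),
    fitted = tibble::tibble(day = day, observed = value, fitted = pred),
    fit = fit
  )
  class(out) <- "hemsim_beta_fit"
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_beta
#' @param x A `hemsim_beta_fit` object.
#' @param ... Unused.
#' @export
tidy.hemsim_beta_fit <- function(x, ...) {
  tidyr::pivot_longer(x$params, dplyr::everything(),
                      names_to = "term", values_to = "estimate")
}

#' @rdname fit_beta
#' @export
glance.hemsim_beta_fit <- function(x, ...) x$metrics

#' @export
print.hemsim_beta_fit <- function(x, ...) {
  cat("<hemsim_beta_fit>\n")
  print(x$params)
  print(x$metrics)
  invisible(x)
}

#' Simulate a noisy organ growth series
#'
#' Fixture generator for calibration studies: samples the cumulative beta
#' curve at regular intervals and adds seeded Gaussian noise proportional to
#' the final size, emulating repeated field measurements of one organ.
#'
#' @param w_max,t0,t_m,t_e Beta growth parameters.
#' @param days Measurement days.
#' @param noise_sd Noise standard deviation as a fraction of `w_max`.
#' @param seed Integer seed.
#' @return Tibble with `day` and `value`.
#' @export
simulate_organ_series <- function(w_max, t0, t_m, t_e,
                                  days = seq(t0, t_e + 6, by = 3),
                                  noise_sd = 0.02, seed = 1) {
  cm <- beta_cm_for_wmax(w_max, t0, t_m, t_e)
  mu <- beta_growth_cumulative(days, t0, t_m, t_e, cm)
  withr_seed(seed, {
    eps <- stats::rnorm(length(days), sd = noise_sd * w_max)
  })
  tibble::tibble(day = days, value = pmax(mu + eps, 0))
}
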