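#' Beta growth function
#'
#' Sigmoid organ growth with a finite growth duration. The potential growth
#' rate at time `t` (days) is
#' `cm * ((te - t) / (te - tm)) * ((t - t0) / (tm - t0))^((tm - t0)/(te - tm))`
#' for `t0 <= t <= te` and 0 outside that window: growth starts at the organ
#' birth day `t0`, peaks at `cm` on day `tm`, and ceases at `te`. The
#' cumulative form integrates the rate in closed form; `beta_cm_for_wmax()`
#' returns the peak rate that makes the organ reach its final size `w_max`
#' exactly at `te`.
#'
#' @param t Time in days (vectorized).
#' @param t0 Birth day of the organ.
#' @param tm Day of maximum growth rate (`t0 < tm < te`).
#' @param te Day growth ceases.
#' @param cm Maximum growth rate (size units per day).
#' @return `beta_growth_rate()`: the potential rate (>= 0);
#'   `beta_growth_cumulative()`: the accumulated size;
#'   `beta_cm_for_wmax()`: the peak rate consistent with `w_max`.
#' @export
#' @examples
#' beta_growth_rate(75, t0 = 0, tm = 50, te = 100, cm = 1) # 0.75
#' beta_growth_cumulative(100, 0, 50, 100, beta_cm_for_wmax(2, 0, 50, 100))
beta_growth_rate <- function(t, t0, tm, te, cm) {
  check_beta_params(t0, tm, te, cm)
  tau <- t - t0
  tau_m <- tm - t0
  tau_e <- te - t0
  rate <- cm * ((tau_e - tau) / (tau_e - tau_m)) * (tau / tau_m)^(tau_m / (tau_e - tau_m))
  rate[t < t0 | t > te] <- 0
  rate[!is.finite(rate)] <- 0
  pmax(rate, 0)
}

#' @rdname beta_growth_rate
#' @export
beta_growth_cumulative <- function(t, t0, tm, te, cm) {
  check_beta_params(t0, tm, te, cm)
  tau <- pmin(pmax(t - t0, 0), te - t0)
  tau_m <- tm - t0
  tau_e <- te - t0
  # closed-form integral of the rate (Yin-type beta growth curve), rescaled
  # from the peak rate that corresponds to a unit final size
  cm_unit <- beta_cm_for_wmax(1, t0, tm, te)
  w_unit <- (1 + (tau_e - tau) / (tau_e - tau_m)) * (tau / tau_e)^(tau_e / (tau_e - tau_m))
  cm / cm_unit * w_unit
}

#' @param w_max Final organ size or mass reached at `te`.
#' @rdname beta_growth_rate
#' @export
beta_cm_for_wmax <- function(w_max, t0, tm, te) {
  stopifnot(all(w_max > 0))
  check_beta_params(t0, tm, te, cm = 1)
  tau_m <- tm - t0
  tau_e <- te - t0
  w_max * (2 * tau_e - tau_m) / (tau_e * (tau_e - tau_m)) *
    (tau_m / tau_e)^(tau_m / (tau_e - tau_m))
}

check_beta_params <- function(t0, tm, te, cm) {
  if (any(!(t0 < tm & tm < te))) {
    stop("beta growth requires t0 < tm < te", call. = FALSE)
  }
  if (any(cm <= 0)) stop("`cm` must be positive", call. = FALSE)
  invisible(TRUE)
}
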