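#' Leaf photosynthesis and gas-exchange parameters
#'
#' C3 parameter set for the coupled leaf model: maximum carboxylation and
#' electron transport rates at 25 C, dark respiration, quantum yield and
#' curvature of the light response, Michaelis constants and CO2 compensation
#' point with their temperature responses (Arrhenius; a peaked function for
#' Jmax), Ball-Woodrow-Berry slope/intercept, and boundary-layer/energy
#' balance constants. The defaults are the packaged daylily calibration;
#' every value can be overridden.
#'
#' @param vcmax25,jmax25 Maximum carboxylation / electron transport rate at
#'   25 C (umol m-2 s-1).
#' @param rd25 Dark respiration at 25 C (umol m-2 s-1).
#' @param alpha Apparent quantum yield (mol e- per mol photons).
#' @param theta Curvature of the non-rectangular hyperbola light response.
#' @param kc25,ko25 Michaelis constants for CO2 (ubar) and O2 (mbar) at 25 C.
#' @param gstar25 CO2 compensation point without dark respiration (ubar).
#' @param ea_vcmax,ea_rd,ea_kc,ea_ko,ea_gstar Activation energies (J mol-1).
#' @param ha_jmax,hd_jmax,ds_jmax Peaked temperature response of Jmax
#'   (J mol-1, J mol-1, J mol-1 K-1).
#' @param bwb_m,bwb_g0 Ball-Woodrow-Berry slope (dimensionless) and intercept
#'   (mol m-2 s-1).
#' @param o2 Oxygen partial pressure (mbar).
#' @param leaf_width Characteristic leaf width for the boundary layer (m).
#' @param emissivity Leaf longwave emissivity.
#' @return Named list of parameters.
#' @export
photosynthesis_params <- function(vcmax25 = 110, jmax25 = 210, rd25 = 1.1,
                                  alpha = 0.30, theta = 0.7,
                                  kc25 = 404.9, ko25 = 278.4, gstar25 = 42.75,
                                  ea_vcmax = 65330, ea_rd = 46390,
                                  ea_kc = 79430, ea_ko = 36380,
                                  ea_gstar = 37830,
                                  ha_jmax = 50000, hd_jmax = 200000,
                                  ds_jmax = 650,
                                  bwb_m = 9, bwb_g0 = 0.01,
                                  o2 = 210, leaf_width = 0.015,
                                  emissivity = 0.97) {
  p <- list(vcmax25 = vcmax25, jmax25 = jmax25, rd25 = rd25, alpha = alpha,
            theta = theta, kc25 = kc25, ko25 = ko25, gstar25 = gstar25,
            ea_vcmax = ea_vcmax, ea_rd = ea_rd, ea_kc = ea_kc, ea_ko = ea_ko,
            ea_gstar = ea_gstar, ha_jmax = ha_jmax, hd_jmax = hd_jmax,
            ds_jmax = ds_jmax, bwb_m = bwb_m, bwb_g0 = bwb_g0, o2 = o2,
            leaf_width = leaf_width, emissivity = emissivity)
  if (any(unlist(p) <= 0) || theta > 1) {
    stop("photosynthesis parameters must be positive (theta in (0,1])", call. = FALSE)
  }
  p
}

RGAS <- 8.314

arrhenius <- function(ea, tleaf_k) {
  exp(ea * (tleaf_k - 298.15) / (298.15 * RGAS * tleaf_k))
}

peaked <- function(ha, hd, ds, tleaf_k) {
  arrhenius(ha, tleaf_k) *
    (1 + exp((298.15 * ds - hd) / (298.15 * RGAS))) /
    (1 + exp((tleaf_k * ds - hd) / (tleaf_k * RGAS)))
}

#' FvCB net assimilation rate
#'
#' Farquhar-von Caemmerer-Berry C3 assimilation: the Rubisco-limited and
#' electron-transport-limited carboxylation rates are evaluated at the leaf
#' temperature (electron transport from a non-rectangular hyperbola of PPFD),
#' the smaller is taken, scaled by `(1 - gstar/ci)` for photorespiration, and
#' dark respiration is subtracted.
#'
#' @param ci Intercellular CO2 (umol mol-1, ~= ubar), > 0.
#' @param ppfd Photosynthetic photon flux density (umol m-2 s-1).
#' @param tleaf Leaf temperature (degrees C).
#' @param p Parameters from [photosynthesis_params()].
#' @return Net assimilation (umol CO2 m-2 s-1); `-Rd` in darkness and at the
#'   compensation point.
#' @export
fvcb_assimilation <- function(ci, ppfd, tleaf, p = photosynthesis_params()) {
  if (any(!is.finite(ci)) || any(!is.finite(ppfd)) || any(!is.finite(tleaf))) {
    stop("non-finite input to the assimilation model", call. = FALSE)
  }
  if (any(ci <= 0)) stop("`ci` must be positive", call. = FALSE)
  tk <- tleaf + 273.15
  kc <- p$kc25 * arrhenius(p$ea_kc, tk)
  ko <- p$ko25 * arrhenius(p$ea_ko, tk)
  gstar <- p$gstar25 * arrhenius(p$ea_gstar, tk)
  vcmax <- p$vcmax25 * arrhenius(p$ea_vcmax, tk)
  rd <- p$rd25 * arrhenius(p$ea_rd, tk)
  jmax <- p$jmax25 * peaked(p$ha_jmax, p$hd_jmax, p$ds_jmax, tk)
  ii <- p$alpha * ppfd
  j <- (ii + jmax - sqrt((ii + jmax)^2 - 4 * p$theta * ii * jmax)) / (2 * p$theta)
  wc <- vcmax * ci / (ci + kc * (1 + p$o2 / ko))
  wj <- (j / 4) * ci / (ci + 2 * gstar)
  pmin(wc, wj) * (1 - gstar / ci) - rd
}

# both limitation terms, for crossover diagnostics
fvcb_limitations <- function(ci, ppfd, tleaf, p = photosynthesis_params()) {
  tk <- tleaf + 273.15
  kc <- p$kc25 * arrhenius(p$ea_kc, tk)
  ko <- p$ko25 * arrhenius(p$ea_ko, tk)
  gstar <- p$gstar25 * arrhenius(p$ea_gstar, tk)
  vcmax <- p$vcmax25 * arrhenius(p$ea_vcmax, tk)
  jmax <- p$jmax25 * peaked(p$ha_jmax, p$hd_jmax, p$ds_jmax, tk)
  ii <- p$alpha * ppfd
  j <- (ii + jmax - sqrt((ii + jmax)^2 - 4 * p$theta * ii * jmax)) / (2 * p$theta)
  list(wc = vcmax * ci / (ci + kc * (1 + p$o2 / ko)),
       wj = (j / 4) * ci / (ci + 2 * gstar))
}

#' Ball-Woodrow-Berry stomatal conductance
#'
#' `gs = g0 + m * A * RH_s / Cs`, floored at `g0` (stomata do not respond to
#' negative assimilation).
#'
#' @param a_net Net assimilation (umol m-2 s-1).
#' @param rh_surface Relative humidity at the leaf surface, fraction.
#' @param cs CO2 at the leaf surface (umol mol-1), > 0.
#' @param p Parameters from [photosynthesis_params()].
#' @return Stomatal conductance to water vapour (mol m-2 s-1).
#' @export
bwb_conductance <- function(a_net, rh_surface, cs, p = photosynthesis_params()) {
  if (any(cs <= 0)) stop("`cs` must be positive", call. = FALSE)
  pmax(p$bwb_g0, p$bwb_g0 + p$bwb_m * pmax(a_net, 0) * rh_surface / cs)
}

# boundary-layer conductance to water vapour (mol m-2 s-1), forced convection
boundary_layer_conductance <- function(wind, leaf_width = 0.015) {
  0.147 * sqrt(pmax(wind, 0.1) / leaf_width)
}

saturation_vp <- function(tc) 611.2 * exp(17.62 * tc / (tc + 243.12)) # Pa

#' Leaf energy balance
#'
#' Solves for the leaf temperature at which absorbed shortwave radiation is
#' balanced by isothermal longwave loss, sensible heat exchange and latent
#' cooling (`R_abs = eps*sigma*(Tl^4 - Ta^4) + cp*gbh*(Tl - Ta) +
#' lambda*gtw*(es(Tl) - ea)/P`), by damped Newton iteration.
#'
#' @param absorbed Absorbed shortwave flux (W m-2 leaf), >= 0.
#' @param tair Air temperature (degrees C).
#' @param wind Wind speed (m s-1).
#' @param gs Stomatal conductance (mol m-2 s-1).
#' @param rh Air relative humidity, fraction.
#' @param p Parameters from [photosynthesis_params()].
#' @param tol Residual tolerance (W m-2).
#' @param max_iter Iteration cap.
#' @return Leaf temperature (degrees C).
#' @export
leaf_energy_balance <- function(absorbed, tair, wind, gs, rh,
                                p = photosynthesis_params(),
                                tol = 0.01, max_iter = 50) {
  if (any(absorbed < 0)) stop("`absorbed` must be non-negative", call. = FALSE)
  sigma <- 5.670374e-8
  cp <- 29.3      # J mol-1 K-1
  lambda <- 44000 # J mol-1
  pres <- 101325
  gb <- boundary_layer_conductance(wind, p$leaf_width)
  gtw <- 1 / (1 / pmax(gs, 1e-6) + 1 / gb)
  ea <- rh * saturation_vp(tair)
  tl <- tair
  ta_k <- tair + 273.15
  for (i in seq_len(max_iter)) {
    tl_k <- tl + 273.15
    es <- saturation_vp(tl)
    resid <- absorbed - p$emissivity * sigma * (tl_k^4 - ta_k^4) -
      cp * gb * (tl - tair) - lambda * gtw * pmax(es - ea, 0) / pres
    des <- es * 17.62 * 243.12 / (tl + 243.12)^2
    dresid <- -4 * p$emissivity * sigma * tl_k^3 - cp * gb -
      lambda * gtw * ifelse(es > ea, des, 0) / pres
    step <- resid / dresid
    tl <- tl - pmax(pmin(step, 5), -5)
    if (all(abs(resid) < tol)) break
  }
  if (i == max_iter && any(abs(resid) >= tol)) {
    warning("leaf energy balance did not reach tolerance", call. = FALSE)
  }
  tl
}

#' Coupled leaf gas exchange
#'
#' Fixed point of the four-equation leaf model: FvCB assimilation,
#' Ball-Woodrow-Berry conductance, CO2 diffusion
#' `Ci = Ca - A * (1.6/gs + 1.37/gb)` and the leaf energy balance, solved by
#' damped successive substitution.
#'
#' @param ppfd Absorbed PPFD (umol m-2 s-1), vectorized.
#' @param tair Air temperature (degrees C).
#' @param rh Relative humidity fraction.
#' @param co2 Ambient CO2 (umol mol-1).
#' @param wind Wind speed (m s-1).
#' @param p Parameters from [photosynthesis_params()].
#' @param tol Relative convergence tolerance on all state variables.
#' @param max_iter Iteration cap; non-converged leaves are flagged.
#' @param damping Successive-substitution damping factor in (0, 1].
#' @return A tibble with `a_net`, `gs`, `ci`, `t_leaf`, `converged` and
#'   `iterations`.
#' @export
#' @examples
#' coupled_leaf_flux(ppfd = 400, tair = 25, rh = 0.6, co2 = 400, wind = 2)
coupled_leaf_flux <- function(ppfd, tair, rh, co2, wind,
                              p = photosynthesis_params(),
                              tol = 1e-4, max_iter = 50, damping = 0.5) {
  n <- max(length(ppfd), length(tair), length(rh), length(co2), length(wind))
  ppfd <- rep_len(ppfd, n); tair <- rep_len(tair, n); rh <- rep_len(rh, n)
  co2 <- rep_len(co2, n); wind <- rep_len(wind, n)
  gb <- boundary_layer_conductance(wind, p$leaf_width)
  absorbed <- ppfd / 2.275
  ci <- 0.7 * co2
  tl <- tair
  gs <- rep_len(p$bwb_g0 + 0.05, n)
  a <- fvcb_assimilation(ci, ppfd, tl, p)
  converged <- rep(FALSE, n)
  iters <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    act <- !converged
    if (!any(act)) break
    a_new <- fvcb_assimilation(ci[act], ppfd[act], tl[act], p)
    cs <- pmax(co2[act] - a_new * 1.37 / gb[act], 50)
    gs_new <- bwb_conductance(a_new, rh[act], cs, p)
    ci_new <- pmin(pmax(co2[act] - a_new * (1.6 / gs_new + 1.37 / gb[act]), 1),
                   co2[act])
    tl_new <- leaf_energy_balance(absorbed[act], tair[act], wind[act],
                                  gs_new, rh[act], p)
    d_a <- abs(a_new - a[act]) / pmax(abs(a_new), 0.1)
    d_gs <- abs(gs_new - gs[act]) / pmax(gs_new, 1e-4)
    d_ci <- abs(ci_new - ci[act]) / pmax(ci_new, 1)
    d_tl <- abs(tl_new - tl[act]) / 10
    a[act] <- a[act] + damping * (a_new - a[act])
    gs[act] <- gs[act] + damping * (gs_new - gs[act])
    ci[act] <- ci[act] + damping * (ci_new - ci[act])
    tl[act] <- tl[act] + damping * (tl_new - tl[act])
    iters[act] <- it
    now_conv <- pmax(pmax(d_a, d_gs), pmax(d_ci, d_tl)) < tol
    idx <- which(act)
    converged[idx[now_conv]] <- TRUE
  }
  # polish onto the fixed point with a few undamped sweeps
  for (k in 1:4) {
    a <- fvcb_assimilation(ci, ppfd, tl, p)
    cs <- pmax(co2 - a * 1.37 / gb, 50)
    gs <- bwb_conductance(a, rh, cs, p)
    ci <- pmin(pmax(co2 - a * (1.6 / gs + 1.37 / gb), 1), co2)
    tl <- leaf_energy_balance(absorbed, tair, wind, gs, rh, p)
  }
  a <- fvcb_assimilation(ci, ppfd, tl, p)
  tibble::tibble(a_net = a, gs = gs, ci = ci, t_leaf = tl,
                 converged = converged, iterations = iters)
}
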