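#' Respiration and carbon-cost parameters
#'
#' @param growth_conversion Glucose cost of structural growth
#'   (g glucose per g dry matter, >= 1); the excess over 1 is growth
#'   respiration.
#' @param maintenance_rate Maintenance respiration
#'   (g glucose per g structural dry matter per day).
#' @param root_fraction Daily root assimilate draw as a fraction of the
#'   remaining central carbon pool, in `[0, 1)`.
#' @return Named list.
#' @export
respiration_params <- function(growth_conversion = 1.39,
                               maintenance_rate = 0.014,
                               root_fraction = 0.15) {
  stopifnot(growth_conversion >= 1, maintenance_rate >= 0,
            root_fraction >= 0, root_fraction < 1)
  list(growth_conversion = growth_conversion,
       maintenance_rate = maintenance_rate,
       root_fraction = root_fraction)
}

#' Fresh-to-dry mass conversion factors
#'
#' Empirical per-organ fresh:dry mass ratios used to report fresh weights.
#'
#' @param leaf,scape,bud Fresh:dry ratios (> 1).
#' @return Named numeric vector.
#' @export
fresh_weight_factors <- function(leaf = 6, scape = 8, bud = 10) {
  f <- c(leaf = leaf, scape = scape, bud = bud)
  if (any(f <= 1)) stop("fresh:dry ratios must exceed 1", call. = FALSE)
  f
}

#' Total daily sink demand
#'
#' Weighted sum over the time step of the potential growth rates of all
#' active organs.
#'
#' @param rates Potential sink strengths (g dry matter per day), >= 0.
#' @param dt Time step in days.
#' @return Total demand (g dry matter).
#' @export
total_demand <- function(rates, dt = 1) {
  if (any(rates < 0)) stop("potential rates must be non-negative", call. = FALSE)
  sum(rates * dt)
}

#' Allocate the assimilate pool to organ growth
#'
#' Each organ receives its proportional share of the pool,
#' `gr_i = (S_i / S_tot) * ap`, capped at its own potential demand
#' `S_i * dt`; surplus assimilate stays in the pool.
#'
#' @param ap Current shared assimilate pool (g glucose-equivalent dry
#'   allocation base), >= 0.
#' @param rates Potential sink strengths (g day-1).
#' @param dt Time step (days).
#' @return Actual growth per organ (g), same length as `rates`.
#' @export
#' @examples
#' allocate(1, c(0.5, 1.5)) # c(0.25, 0.75)
allocate <- function(ap, rates, dt = 1) {
  stopifnot(ap >= 0)
  if (any(rates < 0)) stop("potential rates must be non-negative", call. = FALSE)
  s_tot <- sum(rates * dt)
  if (s_tot <= 0) return(rates * 0)
  pmin(rates / sum(rates) * ap, rates * dt)
}

#' Charge respiration and the root draw to the carbon pool
#'
#' After allocation, the pool pays growth respiration
#' `(growth_conversion - 1) * sum(gr_real)`, maintenance respiration
#' `maintenance_rate * biomass`, and finally the fixed root draw
#' `root_fraction * pool`. The pool is floored at zero; a shortfall is
#' reported as a `shrink` factor by which the day's growth must be scaled
#' back (biomass is never catabolized).
#'
#' @param pool Pool after allocation has been subtracted (g glucose).
#' @param gr_total Total actual growth of the day (g dry matter).
#' @param biomass Structural (above-ground) dry biomass basis for
#'   maintenance (g).
#' @param p Parameters from [respiration_params()].
#' @return List with `pool`, `growth_resp`, `maintenance`, `root` and
#'   `shrink` (1 when the pool covered all charges).
#' @export
respire_and_root <- function(pool, gr_total, biomass, p = respiration_params()) {
  stopifnot(pool >= 0, gr_total >= 0, biomass >= 0)
  growth_resp <- (p$growth_conversion - 1) * gr_total
  maint <- p$maintenance_rate * biomass
  charges <- growth_resp + maint
  if (charges > pool && charges > 0) {
    shrink <- max(0, (pool - maint) / max(growth_resp, 1e-300))
    shrink <- min(1, shrink)
    growth_resp <- growth_resp * shrink
    maint <- min(maint, pool - growth_resp)
    pool <- max(0, pool - growth_resp - maint)
  } else {
    shrink <- 1
    pool <- pool - charges
  }
  root <- p$root_fraction * pool
  list(pool = pool - root, growth_resp = growth_resp, maintenance = maint,
       root = root, shrink = shrink)
}

#' Fresh weight of an organ
#'
#' @param dry_mass Organ dry mass (g).
#' @param kind Organ kind: `"leaf"`, `"scape"` or `"bud"`.
#' @param factors Fresh:dry ratios from [fresh_weight_factors()].
#' @return Fresh mass (g).
#' @export
fresh_weight <- function(dry_mass, kind, factors = fresh_weight_factors()) {
  ratio <- factors[kind]
  if (any(is.na(ratio))) {
    stop("no fresh:dry factor for organ kind: ",
         paste(unique(kind[is.na(ratio)]), collapse = ", "), call. = FALSE)
  }
  unname(ratio * dry_mass)
}

# One atomic daily carbon update for a plant: allocation per the
# proportional-share rule with the growth-conversion cost, then maintenance
# and the root draw. The deficit rule shrinks the day's growth so the pool
# never goes negative; maintenance unpayable even at zero growth is capped at
# the pool (no catabolism). Returns an exactly conserving ledger.
carbon_day_update <- function(pool, rates, biomass, p, dt = 1) {
  gr <- allocate(pool, rates, dt)
  gr_tot <- sum(gr)
  cost <- p$growth_conversion * gr_tot
  maint <- p$maintenance_rate * biomass
  if (cost + maint > pool) {
    s <- if (cost > 0) max(0, (pool - maint) / cost) else 0
    s <- min(1, s)
    gr <- gr * s
    gr_tot <- gr_tot * s
    cost <- p$growth_conversion * gr_tot
    maint <- min(maint, pool - cost)
  }
  pool_after <- pool - cost - maint
  root <- p$root_fraction * pool_after
  list(gr = gr,
       pool = pool_after - root,
       growth_g = gr_tot,
       growth_resp_g = (p$growth_conversion - 1) * gr_tot,
       maint_g = maint,
       root_g = root)
}
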