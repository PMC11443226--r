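#' Season simulation configuration
#'
#' Bundles every tunable of a season run. Defaults are the packaged daylily
#' calibration: 6 shoots per plant, 50 percent scape emergence per shoot,
#' 40 buds per inflorescence, and the default phenology, photosynthesis,
#' optics and respiration parameter sets.
#'
#' @param plot Target plot size (m, across x along rows) for the simulated
#'   periodic tile.
#' @param shoots Shoots per plant.
#' @param emergence_rate Probability that a shoot produces a scape.
#' @param phenology Phenology tibble, see [default_phenology()].
#' @param photo Photosynthesis parameters, see [photosynthesis_params()].
#' @param optics Leaf optics, see [optical_props()].
#' @param resp Respiration parameters, see [respiration_params()].
#' @param fresh_factors Fresh:dry ratios, see [fresh_weight_factors()].
#' @param light Tracer configuration, see [light_config()].
#' @param initial_pool Initial assimilate pool per plant (g glucose),
#'   representing the spring reserve of the perennial rootstock.
#' @param organ_seed_frac Fraction of an organ's final dry mass demanded as
#'   initiation mass on its birth day (bootstraps leaf area so the canopy can
#'   begin assimilating).
#' @param latitude Site latitude (decimal degrees).
#' @param n_facets Parallelogram facets per leaf.
#' @param sla Specific leaf area (m2 g-1).
#' @return Named list of settings.
#' @export
simulation_config <- function(plot = c(2.8, 1.5), shoots = 6,
                              emergence_rate = 0.5,
                              phenology = default_phenology(),
                              photo = photosynthesis_params(),
                              optics = optical_props(),
                              resp = respiration_params(),
                              fresh_factors = fresh_weight_factors(),
                              light = light_config(),
                              initial_pool = 45,
                              organ_seed_frac = 0.8,
                              latitude = 40.13,
                              n_facets = 2,
                              sla = hemsim_sla()) {
  list(plot = plot, shoots = shoots, emergence_rate = emergence_rate,
       phenology = phenology, photo = photo, optics = optics, resp = resp,
       fresh_factors = fresh_factors, light = light,
       initial_pool = initial_pool, organ_seed_frac = organ_seed_frac,
       latitude = latitude, n_facets = n_facets, sla = sla)
}

resolve_scenario <- function(scenario) {
  if (is.numeric(scenario) && length(scenario) == 1) {
    tab <- scenario_table()
    scenario <- tab[tab$id == scenario, ]
    if (nrow(scenario) != 1) stop("unknown scenario id", call. = FALSE)
  }
  scenario
}

#' Initialize a season simulation state
#'
#' Builds the scene, instantiates all organs and sets up the per-plant carbon
#' pools and output accumulators.
#'
#' @param scenario Scenario id (1-36) or a one-row scenario tibble.
#' @param seed Integer seed for the plant-level stochastic draws (scape
#'   emergence, leaf azimuth jitter); a stream independent of the weather
#'   noise.
#' @param config Settings from [simulation_config()].
#' @return A simulation state (list) to be advanced with [simulate_step()].
#' @export
season_init <- function(scenario, seed = 1, config = simulation_config()) {
  scenario <- resolve_scenario(scenario)
  scene <- build_scene(scenario, config$plot)
  organs <- init_plants(scene, config$phenology, config$shoots,
                        config$emergence_rate, seed = seed * 7 + 1)
  n <- nrow(organs)
  st <- list(
    scenario = scenario,
    scene = scene,
    config = config,
    day = NA_integer_,
    organ = list(
      plant = organs$plant, shoot = organs$shoot, kind = organs$organ,
      rank = organs$rank, birth = organs$birth_doy, tm = organs$t_m,
      te = organs$t_e, wlen = organs$w_max_len_m, wdm = organs$w_max_dm_g,
      azimuth = organs$azimuth, x = organs$x, y = organs$y,
      interior = organs$interior,
      cm_len = beta_cm_for_wmax(organs$w_max_len_m, organs$birth_doy,
                                organs$t_m, organs$t_e),
      cm_dm = beta_cm_for_wmax(organs$w_max_dm_g, organs$birth_doy,
                               organs$t_m, organs$t_e),
      dm = numeric(n), dm_pot = numeric(n), len = numeric(n)
    ),
    n_plants = nrow(scene),
    pool = rep(config$initial_pool, nrow(scene)),
    records = list(carbon = list(), canopy = list())
  )
  class(st) <- "hemsim_state"
  st
}

#' Advance the simulation by one day
#'
#' Executes the five daily subprocesses in order: (1) update the sky
#' radiation model from the day's weather; (2) compute per-leaf light
#' interception and coupled leaf photosynthesis; (3) run the source-sink
#' allocation and respiration for every plant; (4) apply the morphology
#' rules (organ activation per the phenology schedule, length extension,
#' leaf area update from new biomass); (5) append the day's output records.
#'
#' @param state State from [season_init()].
#' @param weather_day One row of a weather tibble.
#' @return The advanced state.
#' @export
simulate_step <- function(state, weather_day) {
  if (nrow(weather_day) != 1) stop("`weather_day` must be one row", call. = FALSE)
  cfg <- state$config
  og <- state$organ
  t <- weather_day$doy

  # (1) sky radiation
  h0 <- extraterrestrial_radiation(cfg$latitude, t)
  h <- csrm_daily_radiation(weather_day$tmax_c, weather_day$tmin_c,
                            weather_day$cloud, h0)
  dl_h <- daylength_hours(cfg$latitude, t)
  sun <- mean_sun_position(cfg$latitude, t)
  h_daylight <- if (dl_h > 0) h * 24 / dl_h else 0
  dome <- build_sky_dome(h_daylight, weather_day$cloud,
                         sun$elevation, sun$azimuth)

  # prescribed organ extension (development is calibrated to field endpoints;
  # bud length is mass-coupled and set at summary time)
  grow_len <- og$kind %in% c("leaf", "scape")
  og$len[grow_len] <- beta_growth_cumulative(t, og$birth[grow_len],
                                             og$tm[grow_len], og$te[grow_len],
                                             og$cm_len[grow_len])

  # (2) light interception and leaf gas exchange
  is_leaf <- og$kind == "leaf"
  area <- cfg$sla * og$dm
  live <- which(is_leaf & og$len > 0.005 & area > 1e-6)
  assim_plant <- numeric(state$n_plants)
  ppfd_mean <- 0; tleaf_mean <- NA_real_; anet_mean <- 0; abs_frac <- 0
  tday <- (weather_day$tmax_c + weather_day$tmin_c) / 2
  if (length(live) && h > 0) {
    geom <- scene_leaf_facets(og$len[live], area[live], og$azimuth[live],
                              og$x[live], og$y[live], cfg$n_facets)
    light <- intercept(geom, dome, cfg$optics, cfg$light,
                       tile_size = attr(state$scene, "tile"))
    lv <- light$leaves # ordered by leaf id = index into `live`
    flux <- coupled_leaf_flux(lv$ppfd, tday, weather_day$rh,
                              weather_day$co2_ppm, weather_day$wind_ms,
                              cfg$photo)
    dl_s <- dl_h * 3600
    assim_leaf <- flux$a_net * lv$area * dl_s * 3e-5 # g glucose per leaf day
    assim_plant <- plant_sum(assim_leaf, og$plant[live], state$n_plants)
    w <- lv$area / sum(lv$area)
    ppfd_mean <- sum(lv$ppfd * w)
    tleaf_mean <- sum(flux$t_leaf * w)
    anet_mean <- sum(flux$a_net * w)
    abs_frac <- light$totals$absorbed_w / max(light$totals$incident_w, 1e-9)
  }

  # (3) source-sink allocation, respiration, root draw (per plant, vectorized)
  rates <- beta_growth_rate(t, og$birth, og$tm, og$te, og$cm_dm)
  # leaf initiation: newborn leaves demand a seed mass from the pool so the
  # canopy can bootstrap its area from the spring reserve
  newborn <- og$birth == t & og$kind == "leaf"
  if (any(newborn)) {
    rates[newborn] <- rates[newborn] + cfg$organ_seed_frac * og$wdm[newborn]
  }
  pool <- pmax(state$pool + assim_plant, 0)
  assim_eff <- pool - state$pool
  s_plant <- plant_sum(rates, og$plant, state$n_plants)
  share <- ifelse(s_plant[og$plant] > 0, rates / s_plant[og$plant], 0)
  gr <- pmin(share * pool[og$plant], rates)
  biomass <- plant_sum(og$dm, og$plant, state$n_plants)
  cost <- cfg$resp$growth_conversion * plant_sum(gr, og$plant, state$n_plants)
  maint <- cfg$resp$maintenance_rate * biomass
  over <- cost + maint > pool
  shrink <- rep(1, state$n_plants)
  shrink[over] <- pmin(1, pmax(0, (pool[over] - maint[over]) /
                                 pmax(cost[over], 1e-300)))
  gr <- gr * shrink[og$plant]
  gr_tot <- plant_sum(gr, og$plant, state$n_plants)
  cost <- cfg$resp$growth_conversion * gr_tot
  maint <- pmin(maint, pool - cost)
  pool_after <- pool - cost - maint
  root <- cfg$resp$root_fraction * pool_after
  pool_new <- pool_after - root

  # (4) morphology rules: biomass increment and leaf area refresh
  og$dm <- og$dm + gr
  og$dm_pot <- og$dm_pot + rates

  # (5) output records
  state$records$carbon[[length(state$records$carbon) + 1]] <- list(
    day = t, plant = seq_len(state$n_plants),
    assim_g = assim_eff, growth_g = gr_tot,
    growth_resp_g = (cfg$resp$growth_conversion - 1) * gr_tot,
    maint_g = maint, root_g = root, pool_g = pool_new
  )
  state$records$canopy[[length(state$records$canopy) + 1]] <- list(
    day = t, h_wm2 = h, ppfd_mean = ppfd_mean, tleaf_mean = tleaf_mean,
    anet_mean = anet_mean, absorbed_fraction = abs_frac
  )
  state$organ <- og
  state$pool <- pool_new
  state$day <- t
  state
}

# vectorized leaf facet construction matching build_leaf_geometry()
scene_leaf_facets <- function(len, area, azimuth, x, y, n_facets,
                              base_angle = 75, tip_angle = 15) {
  nl <- length(len)
  leaf_id <- rep(seq_len(nl), each = n_facets)
  fct <- rep(seq_len(n_facets), nl)
  width <- (area / len)[leaf_id]
  seg <- (len / n_facets)[leaf_id]
  ang <- deg2rad(base_angle - (base_angle - tip_angle) * (fct - 0.5) / n_facets)
  az <- deg2rad(azimuth)[leaf_id]
  hx <- sin(az); hy <- cos(az)
  ex <- seg * cos(ang) * hx
  ey <- seg * cos(ang) * hy
  ez <- seg * sin(ang)
  wx <- width * cos(az)
  wy <- -width * sin(az)
  csum0 <- function(v) { # cumulative sum within each leaf, excluding self
    m <- matrix(v, nrow = n_facets)
    out <- m
    out[1, ] <- 0
    if (n_facets > 1) {
      for (j in 2:n_facets) out[j, ] <- out[j - 1, ] + m[j - 1, ]
    }
    as.vector(out)
  }
  x0 <- x[leaf_id] + csum0(ex) - wx / 2
  y0 <- y[leaf_id] + csum0(ey) - wy / 2
  z0 <- csum0(ez)
  nxr <- -ez * wy; nyr <- ez * wx; nzr <- ex * wy - ey * wx
  nrm <- sqrt(nxr^2 + nyr^2 + nzr^2)
  nrm[nrm == 0] <- 1
  flip <- ifelse(nzr < 0, -1, 1)
  tibble::tibble(leaf = leaf_id, facet = fct, x0, y0, z0, ex, ey, ez,
                 wx, wy, wz = 0, area = seg * width,
                 nx = flip * nxr / nrm, ny = flip * nyr / nrm,
                 nz = flip * nzr / nrm)
}

plant_sum <- function(v, plant, n_plants) {
  out <- numeric(n_plants)
  s <- rowsum(v, plant)
  out[as.integer(rownames(s))] <- s
  out
}

#' Run a full season simulation
#'
#' Advances the daily loop over the whole weather series (default: synthetic
#' weather for days 91-242) and summarizes organ growth, carbon fluxes and
#' bud yield.
#'
#' @inheritParams season_init
#' @param weather Weather tibble; `NULL` generates the default synthetic
#'   season with `seed`.
#' @param seed Integer seed shared by the weather generator (when `weather`
#'   is `NULL`) and the plant-level draws.
#' @param ... Settings forwarded to [simulation_config()].
#' @return An object of class `hemsim_season`: a list with `summary`
#'   (yield and calibration endpoints), `plants`, `buds`, `carbon` (daily
#'   ledger), `canopy` (daily scene aggregates), `scene` and `scenario`.
#' @export
#' @examples
#' \donttest{
#' res <- simulate_season(5, seed = 1, plot = c(1.7, 0.7))
#' res$summary$yield_t_ha
#' }
simulate_season <- function(scenario, weather = NULL, seed = 1,
                            config = NULL, ...) {
  if (is.null(config)) config <- simulation_config(...)
  if (is.null(weather)) weather <- generate_synthetic_weather(seed)
  state <- season_init(scenario, seed, config)
  for (i in seq_len(nrow(weather))) {
    state <- simulate_step(state, weather[i, ])
  }
  season_summarize(state)
}

season_summarize <- function(state) {
  cfg <- state$config
  og <- state$organ
  scene <- state$scene
  density <- attr(scene, "density_realized")
  interior <- scene$interior
  if (!any(interior)) interior <- rep(TRUE, nrow(scene)) # degenerate tiny scene

  is_bud <- og$kind == "bud"
  frac <- ifelse(og$dm_pot > 0, pmin(og$dm / og$dm_pot, 1), 0)
  bud_len <- og$wlen * frac^(1 / 3)
  bud_fresh <- fresh_weight(og$dm, "bud", cfg$fresh_factors)

  buds <- tibble::tibble(
    plant = og$plant[is_bud], shoot = og$shoot[is_bud],
    rank = og$rank[is_bud], dm_g = og$dm[is_bud],
    fresh_g = bud_fresh[is_bud], length_m = bud_len[is_bud],
    interior = og$interior[is_bud]
  )
  # per-inflorescence (scape-bearing shoot) bud totals
  infl <- dplyr::summarise(
    dplyr::group_by(buds, .data$plant, .data$shoot),
    fresh_g = sum(.data$fresh_g), n_buds = dplyr::n(),
    interior = .data$interior[1], .groups = "drop"
  )
  infl_int <- infl[infl$interior, ]
  buds_int <- buds[buds$interior, ]

  per_plant_fresh <- plant_sum(buds$fresh_g, buds$plant, state$n_plants)
  plants <- tibble::tibble(
    plant = scene$plant, x = scene$x, y = scene$y, interior = scene$interior,
    bud_fresh_g = per_plant_fresh,
    n_scapes = tabulate_scapes(og, state$n_plants),
    pool_g = state$pool
  )
  scape_sel <- og$kind == "scape"
  scape_len_215 <- if (any(scape_sel)) {
    max(beta_growth_cumulative(215, og$birth[scape_sel], og$tm[scape_sel],
                               og$te[scape_sel], og$cm_len[scape_sel]))
  } else 0
  summary <- list(
    scenario_id = state$scenario$id %||% NA_integer_,
    n_plants = state$n_plants,
    n_interior = sum(scene$interior),
    density_realized = density,
    yield_g_per_plant = mean(plants$bud_fresh_g[interior]),
    yield_g_per_inflorescence = if (nrow(infl_int)) mean(infl_int$fresh_g) else 0,
    yield_t_ha = mean(plants$bud_fresh_g[interior]) * density * 1e-6,
    mean_bud_length_m = if (nrow(buds_int)) mean(buds_int$length_m) else 0,
    mean_buds_per_scape = if (nrow(infl_int)) mean(infl_int$n_buds) else 0,
    scape_len_at_215_m = scape_len_215,
    bud_dm_fraction = if (any(is_bud)) {
      sum(og$dm[is_bud & og$interior]) /
        max(sum(og$dm_pot[is_bud & og$interior]), 1e-12)
    } else 0
  )
  res <- list(
    summary = summary,
    plants = plants,
    buds = buds,
    inflorescences = infl,
    carbon = dplyr::bind_rows(lapply(state$records$carbon, tibble::as_tibble)),
    canopy = dplyr::bind_rows(lapply(state$records$canopy, tibble::as_tibble)),
    organs = organ_snapshot(og, cfg),
    scene = scene,
    scenario = state$scenario,
    config = cfg
  )
  class(res) <- "hemsim_season"
  res
}

tabulate_scapes <- function(og, n_plants) {
  sel <- og$kind == "scape"
  if (!any(sel)) return(integer(n_plants))
  as.integer(plant_sum(rep(1, sum(sel)), og$plant[sel], n_plants))
}

organ_snapshot <- function(og, cfg) {
  frac <- ifelse(og$dm_pot > 0, pmin(og$dm / og$dm_pot, 1), 0)
  len <- ifelse(og$kind == "bud", og$wlen * frac^(1 / 3), og$len)
  tibble::tibble(
    plant = og$plant, shoot = og$shoot, organ = og$kind, rank = og$rank,
    birth_doy = og$birth, length_m = len, dm_g = og$dm,
    dm_potential_g = og$dm_pot,
    area_m2 = ifelse(og$kind == "leaf", cfg$sla * og$dm, NA_real_),
    interior = og$interior
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hemsim_season <- function(x, ...) {
  s <- x$summary
  cat("<hemsim_season> scenario", s$scenario_id, "\n")
  cat(sprintf("  plants %d (interior %d), density %.0f /ha\n",
              s$n_plants, s$n_interior, s$density_realized))
  cat(sprintf("  yield %.1f t/ha; %.1f g/plant; %.1f g/inflorescence\n",
              s$yield_t_ha, s$yield_g_per_plant, s$yield_g_per_inflorescence))
  cat(sprintf("  mean bud length %.3f m; buds/scape %.1f; scape@215 %.2f m\n",
              s$mean_bud_length_m, s$mean_buds_per_scape, s$scape_len_at_215_m))
  invisible(x)
}
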