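#' Leaf area from dry biomass via specific leaf area
#'
#' Leaf area tracks leaf dry matter through a constant specific leaf area,
#' `area = SLA * biomass` with SLA = 0.0023 m2 leaf per g leaf.
#'
#' @param biomass_dm Leaf dry mass in g (vectorized).
#' @param sla Specific leaf area (m2 g-1).
#' @return Leaf area in m2.
#' @export
#' @examples
#' leaf_area_from_biomass(10) # 0.023 m2
leaf_area_from_biomass <- function(biomass_dm, sla = hemsim_sla()) {
  if (any(biomass_dm < 0)) stop("`biomass_dm` must be non-negative", call. = FALSE)
  sla * biomass_dm
}

#' Specific leaf area constant (m2 leaf per g leaf dry mass)
#' @export
hemsim_sla <- function() 0.0023

#' Build the 3D geometry of one leaf
#'
#' A daylily leaf is represented as a chain of parallelogram facets of equal
#' length running tip-to-base along a drooping arc: steep near the base and
#' flatter towards the tip. Facet width is constant at `area / length`, so the
#' facet areas sum exactly to the leaf area.
#'
#' @param length Leaf length (m).
#' @param area Leaf area (m2).
#' @param n_facets Number of parallelogram facets (>= 1).
#' @param base Numeric xyz of the leaf base (m).
#' @param azimuth Leaf azimuth in degrees clockwise from north.
#' @param base_angle,tip_angle Facet inclination above the horizontal at the
#'   base and tip of the leaf (degrees).
#' @return A tibble with one row per facet: base-corner coordinates
#'   (`x0`,`y0`,`z0`), the along-length edge (`ex`,`ey`,`ez`), the width edge
#'   (`wx`,`wy`,`wz`), the facet `area` and outward unit normal
#'   (`nx`,`ny`,`nz`).
#' @export
build_leaf_geometry <- function(length, area, n_facets = 2,
                                base = c(0, 0, 0), azimuth = 0,
                                base_angle = 75, tip_angle = 15) {
  if (n_facets < 1) stop("`n_facets` must be >= 1", call. = FALSE)
  stopifnot(length > 0, area >= 0)
  width <- area / length
  seg <- length / n_facets
  ang <- deg2rad(base_angle - (base_angle - tip_angle) *
                   (seq_len(n_facets) - 0.5) / n_facets)
  az <- deg2rad(azimuth)
  # horizontal direction of the leaf midrib (clockwise-from-north azimuth)
  hx <- sin(az)
  hy <- cos(az)
  ex <- seg * cos(ang) * hx
  ey <- seg * cos(ang) * hy
  ez <- seg * sin(ang)
  # width edge: horizontal, perpendicular to the midrib azimuth
  wx <- width * cos(az)
  wy <- width * -sin(az)
  x0 <- base[1] + c(0, cumsum(ex)[-n_facets]) - wx / 2
  y0 <- base[2] + c(0, cumsum(ey)[-n_facets]) - wy / 2
  z0 <- base[3] + c(0, cumsum(ez)[-n_facets])
  # normal = e x w, normalized and oriented upward
  nxr <- -ez * wy
  nyr <- ez * wx
  nzr <- ex * wy - ey * wx
  nrm <- sqrt(nxr^2 + nyr^2 + nzr^2)
  nrm[nrm == 0] <- 1
  flip <- ifelse(nzr < 0, -1, 1)
  tibble::tibble(
    facet = seq_len(n_facets),
    x0, y0, z0, ex, ey, ez, wx = rep(wx, n_facets), wy = rep(wy, n_facets),
    wz = 0,
    area = seg * width,
    nx = flip * nxr / nrm, ny = flip * nyr / nrm, nz = flip * nzr / nrm
  )
}

#' Lay out a planting scene
#'
#' Positions plants on a periodic tile of the field for one planting
#' configuration. Rows run along the y axis (north-south). `ER` uses
#' equidistant rows at the row spacing; `NWR` alternates wide and narrow
#' inter-row gaps; `DRBR` places paired rows separated by the narrow spacing
#' on ridges that repeat at the wide+narrow period. Edge rows and the first
#' and last plant of each row are flagged as guard (non-interior) plants.
#'
#' @param scenario A one-row scenario tibble or list with `pattern`
#'   ("DRBR", "ER", "NWR"), `wide_row`, `narrow_row` and `plant_spacing` (m).
#' @param plot Numeric length-2 target plot size (x across rows, y along
#'   rows), in m. The realized tile is the smallest whole number of pattern
#'   periods and plant spacings covering it.
#' @return A tibble with columns `plant`, `row`, `x`, `y`, `interior`, plus
#'   attributes `tile` (periodic tile size) and `density_realized`
#'   (plants per hectare on the periodic tile).
#' @export
build_scene <- function(scenario, plot = c(2.8, 1.5)) {
  pattern <- scenario$pattern
  w <- scenario$wide_row
  n <- scenario$narrow_row
  s <- scenario$plant_spacing
  if (any(c(w, s) <= 0) || (pattern != "ER" && n <= 0)) {
    stop("row and plant spacings must be positive", call. = FALSE)
  }
  period <- if (pattern == "ER") w else w + n
  if (plot[1] < period || plot[2] < s) {
    stop("plot smaller than one pattern period", call. = FALSE)
  }
  n_y <- ceiling(plot[2] / s)
  ys <- (seq_len(n_y) - 1) * s
  if (pattern == "ER") {
    n_rows <- ceiling(plot[1] / w)
    xs <- (seq_len(n_rows) - 1) * w
    tile_x <- n_rows * w
  } else if (pattern == "NWR") {
    n_per <- ceiling(plot[1] / period)
    starts <- (seq_len(n_per) - 1) * period
    xs <- as.vector(rbind(starts, starts + w)) # gaps alternate wide, narrow
    tile_x <- n_per * period
  } else if (pattern == "DRBR") {
    n_per <- ceiling(plot[1] / period)
    starts <- (seq_len(n_per) - 1) * period
    xs <- as.vector(rbind(starts, starts + n)) # row pairs `narrow` apart
    tile_x <- n_per * period
  } else {
    stop("unknown planting pattern: ", pattern, call. = FALSE)
  }
  grid <- expand.grid(y = ys, x = xs)
  grid <- grid[order(grid$x, grid$y), ]
  row_id <- match(grid$x, sort(unique(xs)))
  interior <- row_id > 1 & row_id < length(unique(xs)) &
    grid$y > min(ys) & grid$y < max(ys)
  out <- tibble::tibble(
    plant = seq_len(nrow(grid)),
    row = row_id,
    x = grid$x, y = grid$y,
    interior = interior
  )
  attr(out, "tile") <- c(tile_x, n_y * s)
  attr(out, "density_realized") <- nrow(out) / (tile_x * n_y * s) * 1e4
  out
}

#' Initialize the plant population of a scene
#'
#' Instantiates every organ of every plant from a phenology table: each plant
#' carries `shoots` shoots; each shoot carries the full leaf rank series and,
#' with probability `emergence_rate`, one scape with its complement of buds.
#' Organ azimuths follow the opposite (distichous) leaf arrangement per shoot
#' with a small seeded jitter. Organs are created with zero biomass and
#' activate on their birth day.
#'
#' @param positions Scene tibble from [build_scene()].
#' @param phenology Phenology tibble, see [default_phenology()].
#' @param shoots Shoots per plant.
#' @param emergence_rate Probability that a shoot produces a scape.
#' @param seed Integer seed for the emergence and azimuth draws (independent
#'   of the weather stream).
#' @param azimuth_jitter_sd Degrees of azimuth jitter.
#' @return A tibble of organs: `plant`, `shoot`, `organ`, `rank`,
#'   `birth_doy`, `t_m`, `t_e`, `w_max_len_m`, `w_max_dm_g`, `azimuth`,
#'   `x`, `y`, `interior`.
#' @export
init_plants <- function(positions, phenology = default_phenology(),
                        shoots = 6, emergence_rate = 0.5, seed = 1,
                        azimuth_jitter_sd = 8) {
  if (nrow(phenology) == 0) stop("empty phenology schedule", call. = FALSE)
  n_plants <- nrow(positions)
  shoot_grid <- expand.grid(shoot = seq_len(shoots), plant = seq_len(n_plants))
  n_shoots <- nrow(shoot_grid)

  leaves <- phenology[phenology$organ == "leaf", ]
  repro <- phenology[phenology$organ %in% c("scape", "bud"), ]

  n_flower <- round(emergence_rate * shoots)
  withr_seed(seed, {
    # the emergence rate is applied as an exact per-plant fraction with the
    # flowering shoots drawn at random, which keeps the paired scenario
    # design free of binomial noise in the scape count
    flowering <- as.vector(vapply(seq_len(n_plants), function(p) {
      f <- logical(shoots)
      if (n_flower > 0) f[sample.int(shoots, n_flower)] <- TRUE
      f
    }, logical(shoots)))
    shoot_az <- (shoot_grid$shoot - 1) * 360 / shoots +
      stats::rnorm(n_shoots, sd = azimuth_jitter_sd)
    leaf_jit <- stats::rnorm(n_shoots * nrow(leaves), sd = azimuth_jitter_sd)
  })

  rep_shoot <- function(df, keep) {
    idx <- rep(seq_len(nrow(shoot_grid))[keep], each = nrow(df))
    out <- df[rep(seq_len(nrow(df)), sum(keep)), ]
    out$plant <- shoot_grid$plant[idx]
    out$shoot <- shoot_grid$shoot[idx]
    out$shoot_index <- idx
    out
  }
  leaf_org <- rep_shoot(leaves, rep(TRUE, n_shoots))
  # opposite arrangement: alternate ranks flip by 180 degrees
  leaf_org$azimuth <- (shoot_az[leaf_org$shoot_index] +
                         (leaf_org$rank %% 2) * 180 + leaf_jit) %% 360
  organs <- leaf_org
  if (any(flowering) && nrow(repro) > 0) {
    rep_org <- rep_shoot(repro, flowering)
    rep_org$azimuth <- shoot_az[rep_org$shoot_index] %% 360
    organs <- dplyr::bind_rows(leaf_org, rep_org)
  }
  organs$shoot_index <- NULL
  organs$x <- positions$x[organs$plant]
  organs$y <- positions$y[organs$plant]
  organs$interior <- positions$interior[organs$plant]
  tibble::as_tibble(organs[order(organs$plant, organs$shoot, organs$organ,
                                 organs$rank), ])
}
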