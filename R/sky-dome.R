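#' Build the discretized daily sky dome
#'
#' The daily light environment is discretized into 72 diffuse directional
#' sources (6 elevation bands x 12 azimuths covering the hemisphere, weighted
#' by band solid angle times the cosine of the zenith angle) plus one direct
#' sun source aimed at the irradiance-weighted mean solar position. The
#' direct/diffuse split is linear in cloud cover, `f_diffuse = 0.23 +
#' 0.77 * cloud`, anchored at roughly 23 percent diffuse under a clear sky.
#' Source weights are horizontal irradiances and close exactly on the total
#' flux.
#'
#' @param h Daily-mean global horizontal radiation to distribute (W m-2).
#' @param cloud Cloud cover fraction in `[0, 1]`.
#' @param sun_elevation Elevation of the direct source in degrees; the sun
#'   weight is zero when not positive.
#' @param sun_azimuth Azimuth of the direct source in degrees clockwise from
#'   north.
#' @param diffuse_clear Diffuse fraction under a cloud-free sky.
#' @return A tibble with 73 rows and columns `source` ("diffuse"/"sun"),
#'   `elevation`, `azimuth`, `ux`, `uy`, `uz` (unit vector towards the
#'   source), and `weight` (horizontal irradiance, W m-2). The weights sum to
#'   `h` within 1e-9 relative. The total flux is stored in the
#'   `total_flux` attribute.
#' @export
#' @examples
#' dome <- build_sky_dome(300, cloud = 0.4, sun_elevation = 55)
#' sum(dome$weight)
build_sky_dome <- function(h, cloud, sun_elevation, sun_azimuth = 180,
                           diffuse_clear = 0.23) {
  stopifnot(h >= 0, cloud >= 0, cloud <= 1)
  f_diffuse <- min(1, diffuse_clear + (1 - diffuse_clear) * cloud)
  if (sun_elevation <= 0) f_diffuse <- 1

  band_edges <- seq(0, 90, by = 15)
  elev_c <- (band_edges[-7] + band_edges[-1]) / 2
  az_c <- seq(15, 345, by = 30)
  grid <- expand.grid(elevation = elev_c, azimuth = az_c)
  e1 <- deg2rad(band_edges[-7])
  e2 <- deg2rad(band_edges[-1])
  omega_band <- (sin(e2) - sin(e1)) / 12 # per-source solid angle share
  w_rel <- omega_band[match(grid$elevation, elev_c)] * sin(deg2rad(grid$elevation))
  w_diff <- if (sum(w_rel) > 0) w_rel / sum(w_rel) * f_diffuse * h else w_rel * 0

  dome <- tibble::tibble(
    source = c(rep("diffuse", nrow(grid)), "sun"),
    elevation = c(grid$elevation, sun_elevation),
    azimuth = c(grid$azimuth, sun_azimuth),
    weight = c(w_diff, (1 - f_diffuse) * h)
  )
  er <- deg2rad(dome$elevation)
  ar <- deg2rad(dome$azimuth)
  dome$ux <- sin(ar) * cos(er)
  dome$uy <- cos(ar) * cos(er)
  dome$uz <- sin(er)
  dome <- dome[, c("source", "elevation", "azimuth", "ux", "uy", "uz", "weight")]
  attr(dome, "total_flux") <- h
  class(dome) <- c("hemsim_dome", class(dome))
  dome
}
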