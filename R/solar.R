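#' Solar geometry helpers
#'
#' Daily solar geometry at a site: declination, sunset hour angle, daylength,
#' daily-mean extraterrestrial radiation and the irradiance-weighted mean sun
#' position used to aim the direct beam of the sky dome.
#'
#' @name solar
NULL

SOLAR_CONSTANT <- 1367 # W m-2

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Solar declination
#'
#' @param doy Day of year (1-366).
#' @return Declination in radians.
#' @export
solar_declination <- function(doy) {
  deg2rad(23.45) * sin(2 * pi * (284 + doy) / 365)
}

eccentricity_factor <- function(doy) {
  1 + 0.033 * cos(2 * pi * doy / 365)
}

sunset_hour_angle <- function(latitude, doy) {
  phi <- deg2rad(latitude)
  delta <- solar_declination(doy)
  x <- -tan(phi) * tan(delta)
  acos(pmin(1, pmax(-1, x))) # 0 = polar night, pi = polar day
}

#' Daylength in hours
#'
#' @inheritParams solar_declination
#' @param latitude Site latitude in decimal degrees (positive north).
#' @return Daylength in hours.
#' @export
daylength_hours <- function(latitude, doy) {
  24 / pi * sunset_hour_angle(latitude, doy)
}

#' Daily-mean extraterrestrial radiation
#'
#' Standard daily integral of top-of-atmosphere irradiance on a horizontal
#' surface (solar constant 1367 W m-2 with eccentricity and declination
#' corrections), expressed as a 24-h mean flux.
#'
#' @inheritParams daylength_hours
#' @return Daily-mean extraterrestrial radiation H_o in W m-2 (0 during polar
#'   night).
#' @export
#' @examples
#' extraterrestrial_radiation(40.13, 172)
extraterrestrial_radiation <- function(latitude, doy) {
  stopifnot(all(is.finite(latitude)), all(abs(latitude) <= 90),
            all(doy >= 1), all(doy <= 366))
  phi <- deg2rad(latitude)
  delta <- solar_declination(doy)
  ws <- sunset_hour_angle(latitude, doy)
  e0 <- eccentricity_factor(doy)
  h0 <- (SOLAR_CONSTANT / pi) * e0 *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  pmax(h0, 0)
}

#' Instantaneous solar position
#'
#' @inheritParams daylength_hours
#' @param hour Local solar hour (0-24, 12 = solar noon).
#' @return A list with `elevation` and `azimuth` in degrees (azimuth clockwise
#'   from north).
#' @export
solar_position <- function(latitude, doy, hour) {
  phi <- deg2rad(latitude)
  delta <- solar_declination(doy)
  omega <- pi * (hour - 12) / 12
  sin_e <- sin(phi) * sin(delta) + cos(phi) * cos(delta) * cos(omega)
  elev <- asin(pmin(1, pmax(-1, sin_e)))
  # azimuth measured clockwise from north
  az <- atan2(sin(omega) * cos(delta),
              cos(omega) * cos(delta) * sin(phi) - sin(delta) * cos(phi))
  list(elevation = rad2deg(elev), azimuth = (rad2deg(az) + 180) %% 360)
}

#' Irradiance-weighted mean sun position for one day
#'
#' The direct beam of the daily sky dome is aimed at the mean daytime sun
#' position, weighting each instant by the cosine of the solar zenith angle so
#' that high-sun hours dominate, consistent with a single daily light pass.
#'
#' @inheritParams daylength_hours
#' @return A list with `elevation` and `azimuth` in degrees.
#' @export
mean_sun_position <- function(latitude, doy) {
  hours <- seq(0, 24, by = 0.1)
  pos <- solar_position(latitude, doy, hours)
  w <- pmax(sin(deg2rad(pos$elevation)), 0)
  if (sum(w) == 0) {
    return(list(elevation = 0, azimuth = 180))
  }
  elev <- sum(pos$elevation * w) / sum(w)
  az_rad <- deg2rad(pos$azimuth)
  # weighted circular mean keeps the azimuth near solar noon (south at 40 N)
  az <- rad2deg(atan2(sum(sin(az_rad) * w), sum(cos(az_rad) * w))) %% 360
  list(elevation = elev, azimuth = az)
}
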