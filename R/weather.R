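#' Daily surface radiation from cloud cover (CSRM)
#'
#' Cloud-cover-based solar radiation model: the atmospheric transmission ratio
#' is `-0.08 + 0.21 * sqrt(tmax - tmin) - 0.012 * cloud`, clamped to `[0, 1]`
#' (the empirical form can stray outside physical bounds), and applied to the
#' daily-mean extraterrestrial radiation.
#'
#' @param tmax,tmin Daily maximum and minimum air temperature (degrees C).
#' @param cloud Daily mean cloud cover fraction in `[0, 1]`.
#' @param h0 Daily-mean extraterrestrial radiation (W m-2), see
#'   [extraterrestrial_radiation()].
#' @return Daily-mean at-surface global radiation H (W m-2), never exceeding
#'   `h0`.
#' @export
#' @examples
#' csrm_daily_radiation(30, 14, 0.4, 400)
csrm_daily_radiation <- function(tmax, tmin, cloud, h0) {
  if (any(tmax < tmin)) {
    stop("`tmax` must be >= `tmin` for every day", call. = FALSE)
  }
  stopifnot(all(cloud >= 0), all(cloud <= 1), all(h0 >= 0))
  ratio <- -0.08 + 0.21 * sqrt(tmax - tmin) - 0.012 * cloud
  h0 * pmin(1, pmax(0, ratio))
}

#' Convert shortwave flux to photosynthetic photon flux density
#'
#' @param i Absorbed or incident shortwave flux (W m-2).
#' @param factor Conversion factor in umol photons per J (default 2.275).
#' @return PPFD in umol m-2 s-1.
#' @export
radiation_to_ppfd <- function(i, factor = 2.275) {
  if (any(i < 0)) stop("radiative flux must be non-negative", call. = FALSE)
  factor * i
}

#' Generate a synthetic season of daily weather
#'
#' Builds a reproducible daily weather series for the simulated growing season
#' (default days 91-242 at 40.13 N) whose season means match the configured
#' climate statistics: a smooth seasonal temperature course (cosine annual
#' cycle, peak around day 202) plus seeded AR(1) day-to-day noise, constant
#' mean cloudiness with noise, and a diurnal temperature range chosen by
#' inverting the CSRM transmission ratio so that the zero-noise series
#' reproduces the configured mean at-surface radiation exactly.
#'
#' @param seed Integer seed; the series is a pure function of the seed and the
#'   configuration.
#' @param days Integer vector of days of year (default 91:242).
#' @param latitude Site latitude (decimal degrees).
#' @param mean_radiation Target season mean at-surface radiation (W m-2,
#'   24-h mean).
#' @param mean_temp Target season mean air temperature (degrees C).
#' @param mean_cloud Target season mean cloud cover fraction.
#' @param mean_wind Target season mean wind speed (m s-1).
#' @param mean_rh Target season mean relative humidity fraction.
#' @param co2 CO2 concentration (ppm), held constant.
#' @param temp_amplitude Seasonal temperature half-amplitude (degrees C).
#' @param noise Named list of day-to-day noise standard deviations:
#'   `temp`, `range`, `cloud`, `wind`, `rh`. Set all to 0 for the smooth
#'   seasonal curves.
#' @return A tibble with one row per day and columns `doy`, `tmax_c`,
#'   `tmin_c`, `cloud`, `rh`, `co2_ppm`, `wind_ms`.
#' @export
#' @examples
#' w <- generate_synthetic_weather(seed = 1)
#' mean((w$tmax_c + w$tmin_c) / 2)
generate_synthetic_weather <- function(seed,
                                       days = 91:242,
                                       latitude = 40.13,
                                       mean_radiation = 248.7,
                                       mean_temp = 19.1,
                                       mean_cloud = 0.4,
                                       mean_wind = 2.4,
                                       mean_rh = 0.55,
                                       co2 = 415,
                                       temp_amplitude = 9,
                                       noise = list(temp = 1.3, range = 1.5,
                                                    cloud = 0.13, wind = 0.7,
                                                    rh = 0.07)) {
  stopifnot(length(days) >= 2, all(diff(days) == 1))
  if (mean_cloud < 0 || mean_cloud > 1) {
    stop("`mean_cloud` must lie in [0, 1]", call. = FALSE)
  }
  h0 <- extraterrestrial_radiation(latitude, days)
  ratio0 <- mean_radiation / mean(h0)
  if (ratio0 <= 0 || ratio0 > 1) {
    stop("`mean_radiation` is infeasible for this site and season", call. = FALSE)
  }
  # invert the CSRM ratio at the mean cloudiness to fix the mean diurnal range
  root <- (ratio0 + 0.08 + 0.012 * mean_cloud) / 0.21
  if (root <= 0) stop("`mean_radiation` too low to invert the CSRM", call. = FALSE)
  range0 <- root^2

  n <- length(days)
  base <- cos(2 * pi * (days - 202) / 365)
  base <- base - mean(base)

  nz <- function(name) if (is.null(noise[[name]])) 0 else noise[[name]]
  ar1 <- function(sd, phi = 0.6) {
    if (sd == 0) return(rep(0, n))
    e <- stats::rnorm(n, sd = sd * sqrt(1 - phi^2))
    stats::filter(e, phi, method = "recursive")
  }

  # noise is recentred on the configured mean after clamping so the season
  # statistics stay on target for any seed
  center_clamp <- function(v, target, lo, hi) {
    for (i in 1:3) v <- pmin(hi, pmax(lo, v + (target - mean(v))))
    v
  }
  withr_seed(seed, {
    tmean <- mean_temp + temp_amplitude * base + ar1(nz("temp"))
    tmean <- tmean + (mean_temp - mean(tmean))
    trange <- center_clamp(range0 + ar1(nz("range")), range0, 0.5, Inf)
    cloud <- center_clamp(mean_cloud + ar1(nz("cloud")), mean_cloud, 0, 1)
    wind <- center_clamp(mean_wind + ar1(nz("wind")), mean_wind, 0.1, Inf)
    rh <- center_clamp(mean_rh + ar1(nz("rh")), mean_rh, 0.05, 0.99)
  })

  tibble::tibble(
    doy = as.integer(days),
    tmax_c = as.numeric(tmean + trange / 2),
    tmin_c = as.numeric(tmean - trange / 2),
    cloud = as.numeric(cloud),
    rh = as.numeric(rh),
    co2_ppm = co2,
    wind_ms = as.numeric(wind)
  )
}

# evaluate `expr` under a fixed RNG state, restoring the caller's stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval(expr, envir = parent.frame())
}

#' Read or write a daily weather table
#'
#' The on-disk format is a UTF-8 CSV with header
#' `doy,tmax_c,tmin_c,cloud,rh,co2_ppm,wind_ms`, one row per day.
#'
#' @param path File path.
#' @return `read_weather_csv()` returns a weather tibble.
#' @export
read_weather_csv <- function(path) {
  w <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("doy", "tmax_c", "tmin_c", "cloud", "rh", "co2_ppm", "wind_ms")
  missing <- setdiff(need, names(w))
  if (length(missing)) {
    stop("weather file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(w$tmax_c < w$tmin_c)) stop("tmax_c < tmin_c in weather file", call. = FALSE)
  w[need]
}

#' @param weather A weather tibble as produced by [generate_synthetic_weather()].
#' @rdname read_weather_csv
#' @export
write_weather_csv <- function(weather, path) {
  readr::write_csv(weather, path)
  invisible(path)
}
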