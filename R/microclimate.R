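# Hourly microclimate: sinusoidal interpolation of daily extremes, cloud
# attenuation of solar flux, and effective sky radiant temperature.

#' Hourly value on the anchored daily sinusoid
#'
#' Interpolates a daily extreme pair onto an hour-of-day sinusoid. Minimum
#' temperature and wind speed and maximum relative humidity and cloud cover
#' occur at sunrise; maximum temperature and wind speed and minimum relative
#' humidity and cloud cover occur one hour after solar noon. Between anchors
#' the curve is a half-cosine, so it passes exactly through both anchors and
#' is continuous across the day boundary.
#'
#' @param day a one-row data frame (or list) with fields `t_max`, `t_min`,
#'   `wind_max`, `wind_min`, `rh_max`, `rh_min`, `cloud_max`, `cloud_min`.
#' @param variable one of `"temp"`, `"wind"`, `"rh"`, `"cloud"`.
#' @param hour hour of day, 0-23 (decimal allowed); vectorised.
#' @param sun list from [sun_times()] providing `sunrise` and `solar_noon`.
#' @return Interpolated value(s).
#' @export
#' @examples
#' d <- list(t_max = 10, t_min = 2)
#' s <- sun_times(58.77, as.Date("2000-07-01"))
#' hourly_value(d, "temp", s$sunrise, s)  # == 2
hourly_value <- function(day, variable = c("temp", "wind", "rh", "cloud"),
                         hour, sun) {
  variable <- match.arg(variable)
  if (any(hour < 0 | hour >= 24)) abort("hour must lie in [0, 24)")
  ex <- switch(variable,
    temp  = c(a = day$t_min,    b = day$t_max),
    wind  = c(a = day$wind_min, b = day$wind_max),
    rh    = c(a = day$rh_max,   b = day$rh_min),
    cloud = c(a = day$cloud_max, b = day$cloud_min))
  t1 <- sun$sunrise            # anchor A (min temp / max rh)
  t2 <- sun$solar_noon + 1     # anchor B (max temp / min rh)
  rise <- hour >= t1 & hour <= t2
  v <- numeric(length(hour))
  # A -> B half-cosine on the rising branch
  v[rise] <- ex["a"] + (ex["b"] - ex["a"]) *
    (1 - cos(pi * (hour[rise] - t1) / (t2 - t1))) / 2
  # B -> next-day A on the falling branch (wraps past midnight)
  x <- (hour[!rise] - t2) %% 24
  p <- t1 + 24 - t2
  v[!rise] <- ex["b"] + (ex["a"] - ex["b"]) * (1 - cos(pi * x / p)) / 2
  unname(v)
}

#' Cloud attenuation of solar flux
#'
#' Linear attenuation: flux is reduced by `a_max * cloud/100`, reaching the
#' maximum fractional attenuation `a_max` under full overcast. The linear
#' form and the default `a_max = 0.65` are configurable model choices.
#'
#' @param clear_flux clear-sky flux, W/m^2.
#' @param cloud_pct cloud cover, 0-100.
#' @param a_max maximum fractional attenuation at 100% cloud.
#' @return Attenuated flux, W/m^2.
#' @export
cloud_adjust_solar <- function(clear_flux, cloud_pct, a_max = 0.65) {
  if (any(cloud_pct < 0 | cloud_pct > 100)) abort("cloud_pct outside [0, 100]")
  clear_flux * (1 - a_max * cloud_pct / 100)
}

#' Effective sky radiant temperature
#'
#' Combines clear-sky longwave emission from an air-temperature correlation
#' with cloud emission near air temperature, weighted by fractional cloud
#' cover, and converts the blended flux to an effective blackbody
#' temperature. The default clear-sky correlation is Swinbank's
#' (L = 5.31e-13 * T_air^6 W/m^2); the Idso alternative uses vapour
#' pressure from relative humidity.
#'
#' @param t_air air temperature, degC.
#' @param rh relative humidity, % (used by the Idso correlation only).
#' @param cloud_pct cloud cover, 0-100.
#' @param method `"swinbank"` or `"idso"`.
#' @return Effective sky temperature, degC; always <= `t_air`, with the gap
#'   closing as cloud cover rises.
#' @export
#' @examples
#' sky_radiant_temperature(10, 70, 0)
#' sky_radiant_temperature(10, 70, 100)  # ~= air temperature
sky_radiant_temperature <- function(t_air, rh = 50, cloud_pct = 0,
                                    method = c("swinbank", "idso")) {
  method <- match.arg(method)
  tk <- t_air + .const$t0
  l_clear <- switch(method,
    swinbank = 5.31e-13 * tk^6,
    idso = {
      e0 <- 0.01 * rh * sat_vapour_pressure(t_air) / 100 # hPa
      (0.70 + 5.95e-5 * e0 * exp(1500 / tk)) * .const$sigma * tk^4
    })
  l_clear <- pmin(l_clear, .const$sigma * tk^4)
  c <- cloud_pct / 100
  l <- (1 - c) * l_clear + c * .const$sigma * tk^4
  (l / .const$sigma)^0.25 - .const$t0
}

# saturation vapour pressure over water, Pa (Magnus form)
sat_vapour_pressure <- function(t_c) {
  610.94 * exp(17.625 * t_c / (t_c + 243.04))
}

# saturated vapour density, kg/m^3
sat_vapour_density <- function(t_c) {
  sat_vapour_pressure(t_c) / (461.5 * (t_c + .const$t0))
}

#' Hourly microenvironment table
#'
#' Expands a daily climate table (one row per day, see [generate_climate()]
#' or [read_climate_csv()]) into 24 hourly rows per day with air
#' temperature, wind, humidity, cloud, cloud-adjusted solar flux, sky
#' radiant temperature, and substrate surface temperature from the
#' one-dimensional ground column.
#'
#' @param climate daily climate tibble with the `ClimateDay` columns.
#' @param a_max maximum cloud attenuation fraction (see
#'   [cloud_adjust_solar()]).
#' @param ground_props optional property override list passed to
#'   [ground_column()].
#' @return A tibble with one row per (date, hour): columns `date`, `hour`,
#'   `t_air`, `wind`, `rh`, `cloud`, `solar_flux`, `t_sky`, `t_ground`,
#'   `snow`.
#' @export
hourly_microenv <- function(climate, a_max = 0.65, ground_props = NULL) {
  stopifnot(all(c("date", "t_max", "t_min", "latitude") %in% names(climate)))
  hours <- 0:23
  rows <- purrr::map(seq_len(nrow(climate)), function(i) {
    day <- climate[i, ]
    sun <- sun_times(day$latitude, day$date)
    t_air <- hourly_value(day, "temp", hours, sun)
    wind  <- hourly_value(day, "wind", hours, sun)
    rh    <- hourly_value(day, "rh", hours, sun)
    cloud <- hourly_value(day, "cloud", hours, sun)
    clear <- clear_sky_solar(day$latitude, day$longitude, day$date, hours)
    tibble(date = day$date, hour = hours, t_air = t_air, wind = wind,
           rh = rh, cloud = cloud,
           solar_flux = cloud_adjust_solar(clear, cloud, a_max),
           t_sky = sky_radiant_temperature(t_air, rh, cloud),
           snow = day$snow)
  })
  env <- dplyr::bind_rows(rows)
  env$t_ground <- ground_temperature(env, props = ground_props)
  env
}
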