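# Synthetic sub-arctic climate forcing.
#
# Emulates a Churchill-like (western Hudson Bay, 58.77 N) annual cycle:
# a seasonal sinusoid for the daily temperature extremes with shared
# day-to-day anomalies, monthly-constant wind and relative humidity, daily
# cloud cover spanning a configured range (default 30-100%), snow cover
# from October through December, and an optional uniform temperature offset
# for warmed-climate scenarios. It reproduces the structure of the real
# forcing, not any particular year's weather.

#' Churchill-like climate profile
#'
#' Annual-cycle parameters for the synthetic generator. Defaults emulate
#' the Churchill normals: July daily maxima near +18 degC and January
#' maxima near -22 degC, a ~8-10 degC diurnal range, steady ~6 m/s winds,
#' high humidity, cloud ranging 30-100% daily, and snow on the ground from
#' October through December.
#'
#' @param t_max_mean,t_max_amp annual mean and amplitude of the daily
#'   maximum temperature sinusoid, degC.
#' @param t_min_mean,t_min_amp same for the daily minimum.
#' @param phase_day day-of-year of the warmest day.
#' @param wind_monthly,rh_monthly length-12 monthly constants (m/s, %);
#'   used as both daily max and min.
#' @param cloud_range daily cloud span, % (min at midday, max at sunrise).
#' @param snow_months months with snow on the ground.
#' @param noise_sd s.d. of the shared day-to-day temperature anomaly, degC.
#' @param offset uniform offset added to both daily extremes, degC.
#' @param latitude,longitude site coordinates, degrees.
#' @param seed RNG seed making the generated series reproducible.
#' @return list of class `climate_profile`.
#' @export
climate_profile <- function(t_max_mean = -2, t_max_amp = 20,
                            t_min_mean = -11.5, t_min_amp = 18.5,
                            phase_day = 205,
                            wind_monthly = rep(6, 12),
                            rh_monthly = c(72, 72, 74, 78, 80, 80,
                                           78, 80, 82, 84, 84, 78),
                            cloud_range = c(30, 100),
                            snow_months = 10:12,
                            noise_sd = 3, offset = 0,
                            latitude = 58.77, longitude = -94.17,
                            seed = 1L) {
  stopifnot(length(wind_monthly) == 12, length(rh_monthly) == 12,
            cloud_range[1] >= 0, cloud_range[2] <= 100,
            cloud_range[1] <= cloud_range[2])
  structure(as.list(environment()), class = "climate_profile")
}

#' Generate a daily climate series
#'
#' @param profile [climate_profile()] list.
#' @param years calendar years to generate (one tibble row per day).
#' @return Daily climate tibble: `date`, `t_max`, `t_min`, `wind_max`,
#'   `wind_min`, `rh_max`, `rh_min`, `cloud_max`, `cloud_min`, `snow`,
#'   `latitude`, `longitude`. Deterministic for a fixed profile seed;
#'   `t_max >= t_min` on every day by construction (the anomaly is shared
#'   by both extremes).
#' @export
#' @examples
#' cl <- generate_climate(climate_profile(seed = 7), 2000)
#' range(cl$t_max - cl$t_min)
generate_climate <- function(profile, years = 2000) {
  dates <- as.Date(unlist(lapply(years, function(y)
    seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)),
        by = "day"))), origin = "1970-01-01")
  doy <- as.integer(format(dates, "%j"))
  mon <- as.integer(format(dates, "%m"))
  seasonal <- cos(2 * pi * (doy - profile$phase_day) / 365.25)
  anomaly <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(profile$seed)
    rnorm(length(dates), 0, profile$noise_sd)
  })
  tibble(
    date = dates,
    t_max = profile$t_max_mean + profile$t_max_amp * seasonal + anomaly +
      profile$offset,
    t_min = profile$t_min_mean + profile$t_min_amp * seasonal + anomaly +
      profile$offset,
    wind_max = profile$wind_monthly[mon],
    wind_min = profile$wind_monthly[mon],
    rh_max = profile$rh_monthly[mon],
    rh_min = profile$rh_monthly[mon],
    cloud_max = profile$cloud_range[2],
    cloud_min = profile$cloud_range[1],
    snow = mon %in% profile$snow_months,
    latitude = profile$latitude,
    longitude = profile$longitude)
}

#' Read and write the daily climate CSV dialect
#'
#' One row per day with header-named columns `date` (ISO-8601), `tmax_c`,
#' `tmin_c`, `windmax_ms`, `windmin_ms`, `rhmax`, `rhmin`, `cloudmax`,
#' `cloudmin`, `snow`. Coordinates are not part of the dialect and are
#' supplied to the reader (defaulting to Churchill).
#'
#' @param path CSV file path.
#' @param latitude,longitude site coordinates attached to every row.
#' @return `read_climate_csv()`: the daily climate tibble;
#'   `write_climate_csv()`: `path`, invisibly.
#' @export
read_climate_csv <- function(path, latitude = 58.77, longitude = -94.17) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmax_c", "tmin_c", "windmax_ms", "windmin_ms",
            "rhmax", "rhmin", "cloudmax", "cloudmin", "snow")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    abort(paste("climate CSV missing column(s):", paste(missing, collapse = ", ")))
  out <- tibble(
    date = as.Date(raw$date), t_max = raw$tmax_c, t_min = raw$tmin_c,
    wind_max = raw$windmax_ms, wind_min = raw$windmin_ms,
    rh_max = raw$rhmax, rh_min = raw$rhmin,
    cloud_max = raw$cloudmax, cloud_min = raw$cloudmin,
    snow = as.logical(raw$snow),
    latitude = latitude, longitude = longitude)
  if (any(out$t_max < out$t_min)) abort("climate CSV has t_max < t_min")
  if (any(out$wind_max < 0 | out$wind_min < 0)) abort("negative wind speed")
  if (any(out$rh_max > 100 | out$rh_min < 0)) abort("relative humidity outside [0, 100]")
  out
}

#' @rdname read_climate_csv
#' @param climate daily climate tibble.
#' @export
write_climate_csv <- function(climate, path) {
  out <- data.frame(
    date = format(climate$date, "%Y-%m-%d"),
    tmax_c = climate$t_max, tmin_c = climate$t_min,
    windmax_ms = climate$wind_max, windmin_ms = climate$wind_min,
    rhmax = climate$rh_max, rhmin = climate$rh_min,
    cloudmax = climate$cloud_max, cloudmin = climate$cloud_min,
    snow = climate$snow)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the derived hourly microenvironment table
#'
#' @param env hourly tibble from [hourly_microenv()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_hourly_csv <- function(env, path) {
  out <- as.data.frame(env)
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
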