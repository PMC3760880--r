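# Solar geometry and clear-sky irradiance.
#
# Position uses the Spencer Fourier-series declination/eccentricity and the
# hour-angle/zenith relations of standard solar geometry. The clear-sky
# global irradiance combines a Hottel-type beam transmittance
# (0.7^airmass^0.678, Kasten-Young airmass) with the Liu-Jordan diffuse
# fraction. Time throughout is local solar time.

day_angle <- function(date) {
  n <- as.integer(format(as.Date(date), "%j"))
  2 * pi * (n - 1) / 365
}

solar_declination <- function(date) {
  g <- day_angle(date)
  0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
}

sun_eccentricity <- function(date) {
  g <- day_angle(date)
  1.000110 + 0.034221 * cos(g) + 0.001280 * sin(g) +
    0.000719 * cos(2 * g) + 0.000077 * sin(2 * g)
}

# cosine of solar zenith at local solar `hour` (0-24, decimal)
cos_zenith <- function(latitude, date, hour) {
  phi <- latitude * pi / 180
  dec <- solar_declination(date)
  H <- (hour - 12) * 15 * pi / 180
  sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(H)
}

#' Sunrise and solar noon in local solar time
#'
#' Used to anchor the hourly sinusoids. Under polar day or night (no
#' sunrise at the given latitude/date) the anchors fall back to 05:00 and
#' 13:00; at sub-arctic latitudes within the modeled season this guard is
#' never exercised.
#'
#' @param latitude degrees north.
#' @param date calendar date.
#' @return list with `sunrise`, `sunset`, `solar_noon` (decimal hours) and
#'   `polar` flag.
#' @export
sun_times <- function(latitude, date) {
  phi <- latitude * pi / 180
  dec <- solar_declination(date)
  x <- -tan(phi) * tan(dec)
  if (abs(x) > 1) {
    return(list(sunrise = 5, sunset = 21, solar_noon = 13 - 1, polar = TRUE))
  }
  h0 <- acos(x) * 180 / pi / 15
  list(sunrise = 12 - h0, sunset = 12 + h0, solar_noon = 12, polar = FALSE)
}

#' Clear-sky global horizontal irradiance
#'
#' @param latitude,longitude degrees (longitude is accepted for interface
#'   symmetry; local solar time makes the result longitude-independent).
#' @param date calendar date.
#' @param hour local solar hour (0-24, decimal allowed); vectorised.
#' @return Irradiance, W/m^2; zero whenever the sun is at or below the
#'   horizon.
#' @export
#' @examples
#' clear_sky_solar(58.77, -94.17, as.Date("2000-06-21"), 12)
clear_sky_solar <- function(latitude, longitude, date, hour) {
  cz <- cos_zenith(latitude, date, hour)
  out <- numeric(length(cz))
  up <- cz > 0
  if (any(up)) {
    czu <- cz[up]
    zdeg <- acos(pmin(1, czu)) * 180 / pi
    am <- 1 / (czu + 0.50572 * (96.07995 - zdeg)^(-1.6364))
    tb <- 0.7^(am^0.678)
    i0 <- .const$solar_k * sun_eccentricity(date)
    beam <- i0 * czu * tb
    diff <- i0 * czu * pmax(0, 0.271 - 0.294 * tb)
    out[up] <- beam + diff
  }
  out
}
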