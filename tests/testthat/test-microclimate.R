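# Hourly sinusoid interpolation, solar geometry, cloud attenuation, and
# sky radiant temperature.

test_that("hourly sinusoids pass exactly through their anchors", {
  day <- list(t_max = 10, t_min = 2, wind_max = 8, wind_min = 3,
              rh_max = 90, rh_min = 60, cloud_max = 100, cloud_min = 30)
  sun <- sun_times(churchill_lat, as.Date("2000-07-15"))
  peak <- sun$solar_noon + 1
  # minima of temp/wind and maxima of rh/cloud at sunrise
  expect_equal(hourly_value(day, "temp", sun$sunrise, sun), 2)
  expect_equal(hourly_value(day, "wind", sun$sunrise, sun), 3)
  expect_equal(hourly_value(day, "rh", sun$sunrise, sun), 90)
  expect_equal(hourly_value(day, "cloud", sun$sunrise, sun), 100)
  # opposite extremes one hour after solar noon
  expect_equal(hourly_value(day, "temp", peak, sun), 10)
  expect_equal(hourly_value(day, "wind", peak, sun), 8)
  expect_equal(hourly_value(day, "rh", peak, sun), 60)
  expect_equal(hourly_value(day, "cloud", peak, sun), 30)
})

test_that("degenerate sinusoid is constant and curves stay within extremes", {
  sun <- sun_times(churchill_lat, as.Date("2000-07-15"))
  flat <- list(t_max = 5, t_min = 5)
  expect_equal(hourly_value(flat, "temp", 0:23, sun), rep(5, 24))
  day <- list(t_max = 12.5, t_min = -3.5)
  v <- hourly_value(day, "temp", seq(0, 23.9, by = 0.1), sun)
  expect_true(all(v >= -3.5 - 1e-12 & v <= 12.5 + 1e-12))
  # continuity across the midnight wrap of the falling branch
  expect_equal(hourly_value(day, "temp", 23.9999, sun),
               hourly_value(day, "temp", 0, sun), tolerance = 1e-3)
  expect_error(hourly_value(day, "temp", 24, sun), "hour")
})

test_that("clear-sky solar is zero below the horizon and orders solstices", {
  dec <- as.Date("2000-12-21")
  jun <- as.Date("2000-06-21")
  expect_equal(clear_sky_solar(churchill_lat, churchill_lon, dec, 0), 0)
  expect_equal(clear_sky_solar(churchill_lat, churchill_lon, jun, 1), 0)
  expect_gt(clear_sky_solar(churchill_lat, churchill_lon, jun, 12),
            clear_sky_solar(churchill_lat, churchill_lon, dec, 12))
})

test_that("clear-sky solar matches an independent oracle at the equator equinox", {
  # oracle: Haurwitz clear-sky global irradiance, an unrelated empirical
  # closed form G = 1098 cos(z) exp(-0.057 / cos(z)); at the equator at an
  # equinox solar noon the sun is overhead (cos z = 1)
  oracle <- 1098 * exp(-0.057)
  got <- clear_sky_solar(0, 0, as.Date("2000-03-20"), 12)
  expect_lt(abs(got - oracle) / oracle, 0.05)
})

test_that("annual noon clear-sky peak falls within 3 days of the solstice", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2000-12-31"), by = "day")
  noon <- vapply(dates, function(d)
    clear_sky_solar(churchill_lat, churchill_lon, d, 12), numeric(1))
  peak <- dates[which.max(noon)]
  expect_lte(abs(as.numeric(peak - as.Date("2000-06-20"))), 3.5)
})

test_that("cloud attenuation is linear, anchored and monotone", {
  expect_equal(cloud_adjust_solar(800, 0), 800)
  expect_equal(cloud_adjust_solar(800, 100, a_max = 0.65), 800 * 0.35)
  cc <- seq(0, 100, by = 5)
  flux <- cloud_adjust_solar(800, cc)
  expect_true(all(diff(flux) <= 0))
  expect_error(cloud_adjust_solar(800, 101), "cloud")
})

test_that("sky radiant temperature blends Swinbank clear sky with cloud", {
  # overcast sky radiates at air temperature
  expect_lt(abs(sky_radiant_temperature(4, 70, 100) - 4), 2)
  # clear sky against the Swinbank correlation evaluated directly
  tk <- 10 + 273.15
  l <- 5.31e-13 * tk^6
  oracle <- (l / 5.670374419e-8)^0.25 - 273.15
  expect_lt(abs(sky_radiant_temperature(10, 70, 0) - oracle), 0.5)
  # monotone non-decreasing in cloud, never above air temperature
  for (ta in c(-30, -10, 0, 15, 25)) {
    ts <- sky_radiant_temperature(ta, 70, c(0, 30, 70, 100))
    expect_true(all(diff(ts) >= -1e-9))
    expect_true(all(ts <= ta + 1e-6))
  }
})

test_that("hourly microenvironment table has 24 rows per day and dark nights", {
  cl <- fixture_climate()
  week <- cl[cl$date >= as.Date("2000-08-01") & cl$date <= as.Date("2000-08-07"), ]
  env <- hourly_microenv(week)
  expect_equal(nrow(env), 7 * 24)
  expect_true(all(env$solar_flux >= 0))
  expect_true(all(env$solar_flux[env$hour %in% c(0, 23)] == 0))
  expect_true(all(env$t_sky <= env$t_air + 1e-6))
})
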