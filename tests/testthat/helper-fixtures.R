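# Shared fixtures: all built in code, no stored data.

churchill_lat <- 58.77
churchill_lon <- -94.17

# a mid-size average-condition male and his geometry
fixture_bear <- function() init_composition(2.30, 2.25, "male")

fixture_geometry <- function(season = "summer") {
  build_geometry(fixture_bear(), part_specs(season))
}

# a metabolic-chamber microenvironment: sky = air = ground, no sun
chamber_env <- function(t, wind = 1, rh = 50) {
  list(t_air = t, wind = wind, rh = rh, solar_flux = 0,
       t_sky = t, t_ground = t)
}

# an outdoor microenvironment row
outdoor_env <- function(t_air, wind = 4, rh = 70, solar = 0,
                        t_sky = t_air - 15, t_ground = t_air) {
  list(t_air = t_air, wind = wind, rh = rh, solar_flux = solar,
       t_sky = t_sky, t_ground = t_ground)
}

# a free-standing cylindrical part (no joins) for solver unit tests
fixture_cylinder <- function(length = 1, skin_radius = 0.25,
                             fat_thickness = 0.02, fur_depth = 0.04,
                             count = 1L) {
  p <- tibble::tibble(
    part = "cyl", shape = "cylinder", count = count, taper = NA_real_,
    length = length, skin_radius = skin_radius,
    flesh_radius = skin_radius - fat_thickness,
    fat_thickness = fat_thickness, fur_depth = fur_depth,
    fur_radius = skin_radius + fur_depth)
  p$skin_area_lateral <- 2 * pi * skin_radius * length * count
  p$skin_area <- p$skin_area_lateral
  p$fur_area_lateral <- 2 * pi * p$fur_radius * length * count
  p$fur_area <- p$fur_area_lateral
  p
}

# short synthetic climate shared by fasting tests (single generation)
fixture_climate <- local({
  cl <- NULL
  function() {
    if (is.null(cl)) cl <<- generate_climate(climate_profile(seed = 42), 2000)
    cl
  }
})

# assemble an hourly forcing tibble for the ground column
ground_forcing <- function(n_hours, t_air, wind = 2, solar = 0,
                           t_sky = t_air) {
  tibble::tibble(t_air = rep_len(t_air, n_hours),
                 wind = rep_len(wind, n_hours),
                 solar_flux = rep_len(solar, n_hours),
                 t_sky = rep_len(t_sky, n_hours))
}
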