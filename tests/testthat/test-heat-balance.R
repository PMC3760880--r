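# Layered steady-state heat-balance solver.

test_that("fur conductivity rises 7% per m/s and saturates at the cap", {
  expect_equal(fur_conductivity(0.0628, 0), 0.0628)
  expect_equal(fur_conductivity(0.0628, 4), 0.0628 * 1.28)
  w <- 0:6
  expect_equal(diff(fur_conductivity(0.0628, w)), rep(0.07 * 0.0628, 6))
  expect_equal(fur_conductivity(0.0628, 9), fur_conductivity(0.0628, 7))
})

test_that("measured conductance at plausible depth implies ~0.05 W/m.degC", {
  expect_equal(conductance_to_conductivity(1.67, 0.030), 0.0501)
})

test_that("radiant fur temperature sits at 85% of the layer profile", {
  expect_equal(radiant_fur_temperature(20, 20, "linear"), 20)
  expect_equal(radiant_fur_temperature(30, 10, "linear"), 13)
  for (ts in c(-10, 5, 30)) {
    for (tf in c(-25, 0, 12)) {
      tr <- radiant_fur_temperature(ts, tf, "log_annulus",
                                    r_skin = 0.2, r_fur = 0.25)
      expect_gte(tr, min(ts, tf)); expect_lte(tr, max(ts, tf))
    }
  }
})

test_that("respiratory loss follows the ventilation arithmetic", {
  p <- bear_params()
  env <- list(t_air = 0, rh = 50)
  rl <- respiratory_loss(100, p, env)
  expect_equal(rl$ventilation_l_s, 100 / 20100 / 0.2095 / 0.20,
               tolerance = 1e-10)
  # halving extraction doubles ventilation (and nearly doubles the loss)
  p2 <- bear_params(o2_extraction = 0.10)
  rl2 <- respiratory_loss(100, p2, env)
  expect_equal(rl2$ventilation_l_s, 2 * rl$ventilation_l_s)
  expect_equal(rl2$q_resp, 2 * rl$q_resp, tolerance = 1e-9)
  # no thermal or humidity gradient, no loss
  rl0 <- respiratory_loss(100, p, list(t_air = p$t_core, rh = 100))
  expect_lt(abs(rl0$q_resp), 0.5)
})

test_that("fat annulus conduction matches the closed form", {
  # huge flesh conductivity isolates the fat annulus in the core chain
  p <- bear_params()
  p$k_flesh <- 1e9
  cyl <- fixture_cylinder(length = 1, skin_radius = 0.25, fat_thickness = 0.05)
  env <- chamber_env(-10, wind = 2)
  t_skin <- 20
  fx <- polarfast:::part_fluxes_at(t_skin, as.list(cyl), env, p)
  q_expected <- 2 * pi * p$k_fat * 1 * (p$t_core - t_skin) /
    log(0.25 / 0.20)
  expect_equal(fx$q_gen, q_expected, tolerance = 1e-6)
})

test_that("an isothermal environment at core temperature produces no flux", {
  p <- bear_params(skin_wet_fraction = 0)
  cyl <- fixture_cylinder()
  sol <- solve_part(cyl, chamber_env(p$t_core), p)
  expect_lt(abs(sol$q_fur), 1e-6)
  expect_lt(abs(sol$q_gen), 1e-6)
})

test_that("every solved part satisfies the steady-state identity", {
  p <- bear_params()
  g <- fixture_geometry("winter")
  envs <- list(chamber_env(-25, wind = 5), chamber_env(10),
               outdoor_env(-5, solar = 300, t_ground = -2),
               outdoor_env(20, wind = 1, solar = 600, t_ground = 25))
  for (env in envs) {
    bal <- whole_animal(g, env, p)
    tol <- 1e-4 * max(1, bal$whole$q_gen)
    expect_lt(abs((bal$whole$q_gen - bal$whole$q_resp - bal$whole$q_evap) -
                    bal$whole$q_fur), tol)
    expect_lt(abs(bal$whole$q_fur -
                    (bal$whole$q_rad + bal$whole$q_conv - bal$whole$q_sol)), tol)
    # whole-animal fluxes are sums over parts
    for (fld in c("q_gen", "q_evap", "q_fur", "q_rad", "q_conv", "q_sol"))
      expect_equal(bal$whole[[fld]], sum(bal$parts[[fld]]), tolerance = 1e-9)
  }
})

test_that("solver agrees with a nested-bisection brute-force oracle", {
  # oracle: outer bisection on skin temperature, inner bisection on the fur
  # surface temperature from the surface balance, using the same flux
  # equations but none of the solver's closed-form chaining
  oracle_solve <- function(part, env, p) {
    part <- as.list(part)
    r_s <- part$skin_radius
    r_o <- r_s + part$fur_depth
    l <- part$length; n <- part$count
    k_fur <- fur_conductivity(p$k_fur_still, env$wind,
                              p$fur_wind_gain, p$fur_wind_cap)
    fur_cond <- function(ts, tf)
      2 * pi * k_fur * l * n * (ts - tf) / log(r_o / r_s)
    surface_resid <- function(ts, tf) {
      h <- polarfast:::convection_h(2 * r_o, env$wind, tf, env$t_air)
      q_conv <- h * part$fur_area * (tf - env$t_air)
      tr <- radiant_fur_temperature(ts, tf, "log_annulus", r_s, r_o)
      q_rad <- p$emissivity * 5.670374419e-8 * part$fur_area *
        ((tr + 273.15)^4 - 0.5 * (env$t_sky + 273.15)^4 -
           0.5 * (env$t_ground + 273.15)^4)
      q_sol <- (1 - p$hair_reflectivity) * env$solar_flux *
        0.5 * part$fur_area_lateral
      fur_cond(ts, tf) + q_sol - q_conv - q_rad
    }
    skin_resid <- function(ts) {
      tf <- uniroot(function(tf) surface_resid(ts, tf),
                    c(ts - 150, ts + 150), tol = 1e-10)$root
      r_core <- 1 / (4 * pi * p$k_flesh * l * n) +
        log(r_s / (r_s - part$fat_thickness)) / (2 * pi * p$k_fat * l * n)
      q_gen <- (p$t_core - ts) / r_core
      h0 <- polarfast:::convection_h(2 * r_o, env$wind, ts, env$t_air)
      rho <- 101325 / (287.05 * ((ts + env$t_air) / 2 + 273.15))
      q_evap <- p$skin_wet_fraction * part$skin_area * (h0 / (rho * 1006)) *
        (polarfast:::sat_vapour_density(ts) -
           env$rh / 100 * polarfast:::sat_vapour_density(env$t_air)) * 2.45e6
      q_gen - q_evap - fur_cond(ts, tf)
    }
    ts <- uniroot(skin_resid, c(env$t_air - 60, p$t_core - 1e-9),
                  tol = 1e-10)$root
    r_core <- 1 / (4 * pi * p$k_flesh * l * n) +
      log(r_s / (r_s - part$fat_thickness)) / (2 * pi * p$k_fat * l * n)
    (p$t_core - ts) / r_core
  }

  set.seed(101)
  agree <- 0
  for (i in 1:20) {
    cyl <- fixture_cylinder(
      length = runif(1, 0.3, 1.8),
      skin_radius = runif(1, 0.05, 0.3),
      fat_thickness = runif(1, 0.005, 0.04),
      fur_depth = runif(1, 0.01, 0.06))
    env <- chamber_env(runif(1, -30, 15), wind = runif(1, 0.5, 7),
                       rh = runif(1, 30, 95))
    p <- bear_params(k_flesh = runif(1, 0.4, 2.8))
    got <- solve_part(cyl, env, p)$q_gen
    want <- oracle_solve(cyl, env, p)
    expect_lt(abs(got - want) / max(abs(want), 1e-9), 0.001)
  }
})

test_that("curling reduces metabolic demand in the cold", {
  p <- bear_params()
  g <- fixture_geometry("winter")
  env <- chamber_env(-25, wind = 5)
  q_un <- whole_animal(g, env, p, posture = "uncurled")$whole$q_gen
  q_cu <- whole_animal(g, env, p, posture = "curled")$whole$q_gen
  expect_lt(q_cu, q_un)
})

test_that("chamber metabolic rate is non-increasing below thermoneutrality", {
  g <- fixture_geometry("summer")
  sweep <- chamber_sweep(g, seq(-40, 20, by = 5), bear_params(), wind = 4)
  expect_true(all(diff(sweep$q_gen) <= 1e-6))
})

test_that("night solar flux contributes nothing to the balance", {
  p <- bear_params()
  g <- fixture_geometry("summer")
  env_dark <- outdoor_env(5, solar = 0)
  bal <- whole_animal(g, env_dark, p)
  expect_equal(bal$whole$q_sol, 0)
})
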