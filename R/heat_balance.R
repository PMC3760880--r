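# Steady-state layered heat balance.
#
# Per part, metabolic heat generated in the flesh cylinder conducts through
# the subcutaneous fat annulus to the skin, then through the fur layer
# (effective conductivity folding still-air conduction and radiation, with
# a wind-dependent gain), and leaves the fur surface by convection and by
# thermal radiation exchanged at the fur's effective radiant temperature
# (85% of the way along the skin-to-surface profile), offset by absorbed
# solar load. The solved quantity is the generation rate q_gen that keeps
# the core at its set temperature:
#   q_gen - q_resp - q_evap = q_fur = q_rad + q_conv - q_sol.
# The solver is a bracketed scalar root-find on skin temperature with
# closed-form layer relations inside; it is deterministic.

#' Wind-adjusted fur thermal conductivity
#'
#' Still-air conductivity increased linearly by `gain` per m/s of wind,
#' saturating at the `cap` wind speed (default 7% per m/s up to 7 m/s).
#'
#' @param k_still still-air conductivity, W/m.degC.
#' @param wind wind speed, m/s.
#' @param gain fractional increase per m/s.
#' @param cap wind speed at which the increase saturates, m/s.
#' @return Effective fur conductivity, W/m.degC.
#' @export
#' @examples
#' fur_conductivity(0.0628, 4)  # 0.0628 * 1.28
fur_conductivity <- function(k_still, wind, gain = 0.07, cap = 7) {
  if (any(wind < 0)) abort("wind must be non-negative")
  k_still * (1 + gain * pmin(wind, cap))
}

#' Fur conductance to conductivity
#'
#' Converts a measured whole-layer conductance (W/m^2.degC) at a known fur
#' depth into the equivalent conductivity (W/m.degC): `k = conductance *
#' depth` for a planar layer.
#'
#' @param conductance layer conductance, W/m^2.degC.
#' @param depth fur depth, m.
#' @return Conductivity, W/m.degC.
#' @export
#' @examples
#' conductance_to_conductivity(1.67, 0.030)  # ~0.05
conductance_to_conductivity <- function(conductance, depth) {
  conductance * depth
}

#' Effective radiant fur temperature
#'
#' Radiative exchange happens at depth within the porous fur; the model
#' uses the temperature 85% of the way along the skin-to-fur-surface
#' profile. With the default annular-conduction profile the temperature is
#' logarithmic in radius; a linear profile is available for planar layers.
#'
#' @param t_skin,t_fur_surface layer boundary temperatures, degC.
#' @param profile `"log_annulus"` or `"linear"`.
#' @param r_skin,r_fur skin and fur outer radii (m; annulus profile only).
#' @param frac fractional depth (default 0.85).
#' @return Radiant temperature, degC, always between the two boundaries.
#' @export
#' @examples
#' radiant_fur_temperature(30, 10, "linear")  # 13
radiant_fur_temperature <- function(t_skin, t_fur_surface,
                                    profile = c("log_annulus", "linear"),
                                    r_skin = NULL, r_fur = NULL,
                                    frac = 0.85) {
  profile <- match.arg(profile)
  if (profile == "linear" || is.null(r_skin)) {
    t_skin + frac * (t_fur_surface - t_skin)
  } else {
    r <- r_skin + frac * (r_fur - r_skin)
    t_skin + (t_fur_surface - t_skin) * log(r / r_skin) / log(r_fur / r_skin)
  }
}

# air properties at a film temperature (degC)
air_props <- function(t_c) {
  # clamp: trial temperatures at bracket edges can be unphysical
  tk <- pmax(t_c + .const$t0, 120)
  list(k = 0.0243 * (tk / .const$t0)^0.9,
       nu = 1.33e-5 * (tk / .const$t0)^1.7,
       pr = 0.71,
       rho = 101325 / (287.05 * tk))
}

# convective coefficient for a cylinder in crossflow (Hilpert power law)
# with a free-convection floor; D = outer fur diameter
convection_h <- function(d, wind, t_surface, t_air) {
  tf <- max((t_surface + t_air) / 2 + 273.15, 120)   # film temp, K, clamped
  k_air <- 0.0243 * (tf / 273.15)^0.9
  nu_air <- 1.33e-5 * (tf / 273.15)^1.7
  pr <- 0.71
  re <- max(wind, 0.05) * d / nu_air
  cm <- if (re < 4) c(0.989, 0.330) else if (re < 40) c(0.911, 0.385) else
    if (re < 4000) c(0.683, 0.466) else if (re < 40000) c(0.193, 0.618) else
      c(0.027, 0.805)
  nu_forced <- cm[1] * re^cm[2] * pr^(1/3)
  gr <- 9.81 * abs(t_surface - t_air) / tf * d^3 / nu_air^2
  nu_free <- 0.53 * max(gr * pr, 0)^0.25
  max(nu_forced, nu_free) * k_air / d
}

#' Respiratory heat loss
#'
#' Ventilation is set by the oxygen demand of the metabolic rate and the
#' oxygen extraction efficiency; respiratory loss is the sensible warming
#' of inspired air to core temperature plus the latent load of saturating
#' it at core temperature, less the inspired vapour content. Lowering the
#' extraction efficiency (panting) raises ventilation and hence the loss.
#'
#' @param q_gen_total whole-animal metabolic rate, W (> 0).
#' @param params [bear_params()] list (uses `o2_extraction`, `t_core`,
#'   `e_per_l_o2`).
#' @param env list/row with `t_air` (degC) and `rh` (%).
#' @return list with `q_resp` (W) and `ventilation_l_s` (L/s).
#' @export
#' @examples
#' respiratory_loss(100, bear_params(), list(t_air = 0, rh = 70))
respiratory_loss <- function(q_gen_total, params, env) {
  stopifnot(q_gen_total > 0)
  if (params$o2_extraction < params$o2_extraction_min - 1e-12 ||
      params$o2_extraction > 0.20 + 1e-12)
    abort("o2_extraction outside bounds")
  vent <- q_gen_total / params$e_per_l_o2 / .const$o2_frac / params$o2_extraction
  v_m3 <- vent / 1000
  ap <- air_props(env$t_air)
  sensible <- v_m3 * ap$rho * .const$cp_air * (params$t_core - env$t_air)
  rho_v_in <- env$rh / 100 * sat_vapour_density(env$t_air)
  latent <- v_m3 * .const$lambda_vap *
    (sat_vapour_density(params$t_core) - rho_v_in)
  list(q_resp = sensible + latent, ventilation_l_s = vent)
}

# effective conduction radius for a part (truncated cone uses the mean of
# its two end radii)
effective_radius <- function(part) {
  if (part$shape == "truncated_cone")
    part$skin_radius * (1 + part$taper) / 2
  else part$skin_radius
}

# temperature-independent terms for one part in one microenvironment;
# precomputed once per solve so the residual stays cheap
part_context <- function(part, env, params, shade = 0, resp_fraction = 0) {
  l <- part$length
  n <- part$count
  r_s <- effective_radius(part)
  r_flesh <- r_s - part$fat_thickness
  r_o <- r_s + part$fur_depth
  r_core <- 1 / (4 * pi * params$k_flesh * l * n)
  if (part$fat_thickness > 0)
    r_core <- r_core + log(r_s / r_flesh) / (2 * pi * params$k_fat * l * n)
  k_fur <- fur_conductivity(params$k_fur_still, env$wind,
                            params$fur_wind_gain, params$fur_wind_cap)
  list(part = part, env = env, params = params, shade = shade,
       resp_fraction = resp_fraction,
       r_s = r_s, r_o = r_o, r_core = r_core,
       fur_resist = log(r_o / r_s) / (2 * pi * k_fur * l * n),
       # radiant-depth weight for the logarithmic annulus profile
       rad_w = log((r_s + 0.85 * (r_o - r_s)) / r_s) / log(r_o / r_s),
       rho_v_air = env$rh / 100 * sat_vapour_density(env$t_air),
       sky4 = 0.5 * (env$t_sky + .const$t0)^4 +
         0.5 * (env$t_ground + .const$t0)^4,
       q_sol = (1 - params$hair_reflectivity) * env$solar_flux *
         0.5 * part$fur_area_lateral * (1 - shade))
}

# flux terms for one part at a trial skin temperature
part_fluxes_ctx <- function(t_skin, ctx) {
  part <- ctx$part; env <- ctx$env; params <- ctx$params
  q_gen <- (params$t_core - t_skin) / ctx$r_core
  # cutaneous evaporation from the wetted skin fraction (Lewis analogy)
  h0 <- convection_h(2 * ctx$r_o, env$wind, t_skin, env$t_air)
  rho_film <- 101325 / (287.05 * max((t_skin + env$t_air) / 2 + .const$t0, 120))
  h_m <- h0 / (rho_film * .const$cp_air)
  q_evap <- params$skin_wet_fraction * part$skin_area * h_m *
    (sat_vapour_density(t_skin) - ctx$rho_v_air) * .const$lambda_vap
  q_fur <- q_gen * (1 - ctx$resp_fraction) - q_evap
  t_fs <- t_skin - q_fur * ctx$fur_resist
  # exchange at the fur surface
  h <- convection_h(2 * ctx$r_o, env$wind, t_fs, env$t_air)
  q_conv <- h * part$fur_area * (t_fs - env$t_air)
  t_rad <- t_skin + (t_fs - t_skin) * ctx$rad_w
  trk <- max(t_rad + .const$t0, 50)  # kelvin floor for wild trial points
  q_rad <- params$emissivity * .const$sigma * part$fur_area *
    (trk^4 - ctx$sky4)
  list(q_gen = q_gen, q_evap = q_evap, q_fur = q_fur, q_conv = q_conv,
       q_rad = q_rad, q_sol = ctx$q_sol, t_skin = t_skin,
       t_fur_surface = t_fs, t_fur_radiant = t_rad,
       residual = q_fur - (q_rad + q_conv - ctx$q_sol))
}

# flux terms for one part at a trial skin temperature; shared by the
# production solver and the brute-force verification path
part_fluxes_at <- function(t_skin, part, env, params, shade = 0,
                           resp_fraction = 0) {
  part_fluxes_ctx(t_skin, part_context(part, env, params, shade, resp_fraction))
}

#' Solve the steady-state heat balance for one body part
#'
#' Finds the skin temperature (and hence generation rate) at which heat
#' conducted out through fat and fur equals the net radiative + convective
#' loss minus absorbed solar load, for the current hour's microenvironment.
#'
#' @param part one row of a [build_geometry()] tibble (as list or tibble).
#' @param env microenvironment row: `t_air`, `wind`, `rh`, `solar_flux`,
#'   `t_sky`, `t_ground` (degC, m/s, %, W/m^2).
#' @param params [bear_params()] list.
#' @param shade fraction of solar load removed by shade (0 or 1).
#' @param resp_fraction fraction of generation lost via respiration
#'   (supplied by the whole-animal outer iteration).
#' @param bracket skin-temperature search interval, degC.
#' @return One-row tibble of fluxes (W) and layer temperatures (degC).
#' @export
solve_part <- function(part, env, params, shade = 0, resp_fraction = 0,
                       bracket = NULL) {
  fx <- solve_part_list(as.list(part), as.list(env), params, shade,
                        resp_fraction, bracket)
  tibble(part = fx$part %||% NA_character_,
         q_gen = fx$q_gen, q_resp = fx$q_resp,
         q_evap = fx$q_evap, q_fur = fx$q_fur, q_rad = fx$q_rad,
         q_conv = fx$q_conv, q_sol = fx$q_sol,
         t_skin = fx$t_skin, t_fur_surface = fx$t_fur_surface,
         t_fur_radiant = fx$t_fur_radiant)
}

# internal fast path: plain-list result, no tibble allocation
solve_part_list <- function(part, env, params, shade = 0, resp_fraction = 0,
                            bracket = NULL) {
  lo <- bracket[1] %||% (min(env$t_air, params$t_core) - 80)
  hi <- bracket[2] %||% (params$t_core + 30)
  ctx <- part_context(part, env, params, shade, resp_fraction)
  f <- function(t) part_fluxes_ctx(t, ctx)$residual
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    abort(sprintf(
      "no steady-state solution for part '%s' in bracket [%.1f, %.1f] (residuals %.3g / %.3g)",
      part$part %||% "part", lo, hi, flo, fhi))
  root <- uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi, tol = 1e-7)
  fx <- part_fluxes_ctx(root$root, ctx)
  fx$part <- part$part %||% NA_character_
  fx$q_resp <- fx$q_gen * resp_fraction
  fx
}

#' Whole-animal steady-state heat balance
#'
#' Solves every exchanging body part and sums the fluxes. Respiratory loss
#' is computed at the whole-animal level from the summed generation and the
#' oxygen extraction efficiency, and fed back as a per-part generation
#' fraction until generation and respiratory loss are jointly consistent.
#' In the curled posture the legs are tucked into the torso and removed
#' from exchange (and from generation) to minimise exposed surface area.
#'
#' @param parts geometry tibble from [build_geometry()].
#' @param env microenvironment row.
#' @param params [bear_params()] list.
#' @param posture `"uncurled"` or `"curled"`.
#' @param shade fraction of solar load removed (0 or 1).
#' @param tol convergence tolerance on the respiratory fraction.
#' @param rf_init warm start for the respiratory fraction (e.g. carried
#'   over from the previous hour).
#' @return list of class `bear_balance`: `whole` (one-row flux tibble,
#'   including `ventilation_l_s`), `parts` (per-part fluxes),
#'   `resp_fraction`.
#' @export
whole_animal <- function(parts, env, params, posture = c("uncurled", "curled"),
                         shade = 0, tol = 1e-6, rf_init = 0) {
  posture <- match.arg(posture)
  bal <- whole_animal_list(geometry_parts(parts), env, params, posture,
                           shade, tol, rf_init)
  balance_as_tibbles(bal)
}

# convert a geometry tibble to a list of per-part lists once (cached on the
# tibble so repeated solves do not pay the row-conversion cost)
geometry_parts <- function(parts) {
  if (!is.data.frame(parts)) return(parts)
  cached <- attr(parts, "part_list")
  if (!is.null(cached)) return(cached)
  lapply(seq_len(nrow(parts)), function(i) as.list(parts[i, ]))
}

# fast path used by the thermoregulation cascade: everything stays a list
whole_animal_list <- function(part_list, env, params,
                              posture = "uncurled", shade = 0,
                              tol = 1e-6, rf_init = 0) {
  if (posture == "curled")
    part_list <- part_list[!vapply(part_list, function(p)
      p$part %in% c("front_leg", "hind_leg"), logical(1))]
  env <- as.list(env)
  rf <- rf_init
  for (it in 1:30) {
    sol <- lapply(part_list, solve_part_list, env = env, params = params,
                  shade = shade, resp_fraction = rf)
    q_total <- sum(vapply(sol, `[[`, numeric(1), "q_gen"))
    rl <- respiratory_loss(max(q_total, 1e-6), params, env)
    rf_new <- max(min(rl$q_resp / max(q_total, 1e-6), 0.9), -0.9)
    if (abs(rf_new - rf) < tol) { rf <- rf_new; break }
    rf <- rf_new
  }
  sum_of <- function(fld) sum(vapply(sol, `[[`, numeric(1), fld))
  list(q_gen = sum_of("q_gen"), q_resp = rf * sum_of("q_gen"),
       q_evap = sum_of("q_evap"), q_fur = sum_of("q_fur"),
       q_rad = sum_of("q_rad"), q_conv = sum_of("q_conv"),
       q_sol = sum_of("q_sol"), ventilation_l_s = rl$ventilation_l_s,
       sol = sol, resp_fraction = rf, posture = posture, shade = shade)
}

# assemble the user-facing tibbles from a list-form balance
balance_as_tibbles <- function(bal) {
  whole <- tibble(
    part = "whole", q_gen = bal$q_gen, q_resp = bal$q_resp,
    q_evap = bal$q_evap, q_fur = bal$q_fur, q_rad = bal$q_rad,
    q_conv = bal$q_conv, q_sol = bal$q_sol,
    t_skin = NA_real_, t_fur_surface = NA_real_, t_fur_radiant = NA_real_,
    ventilation_l_s = bal$ventilation_l_s)
  keep <- c("part", "q_gen", "q_resp", "q_evap", "q_fur", "q_rad", "q_conv",
            "q_sol", "t_skin", "t_fur_surface", "t_fur_radiant")
  parts_tbl <- dplyr::bind_rows(lapply(bal$sol, function(x) as_tibble(x[keep])))
  structure(list(whole = whole, parts = parts_tbl,
                 resp_fraction = bal$resp_fraction,
                 posture = bal$posture, shade = bal$shade),
            class = "bear_balance")
}

#' Metabolic-chamber sweep
#'
#' Places the bear in a simulated metabolic chamber -- sky, air and ground
#' temperatures all equal, no sun -- and sweeps the chamber temperature,
#' returning the steady-state metabolic rate at each point. With
#' `regulate = TRUE` the thermoregulation cascade runs at each temperature.
#'
#' @param geometry parts tibble from [build_geometry()].
#' @param temps chamber temperatures to sweep, degC.
#' @param params [bear_params()] list.
#' @param wind chamber wind speed, m/s.
#' @param rh chamber relative humidity, %.
#' @param regulate engage the thermoregulation cascade.
#' @param target target metabolic rate, W (needed when `regulate = TRUE`).
#' @param config [thermo_config()] list.
#' @param band_tolerance accepted fractional deviation from target.
#' @return A tibble of class `bear_chamber`: one row per temperature with
#'   `q_gen` and, when regulating, the engaged state.
#' @export
chamber_sweep <- function(geometry, temps, params = bear_params(), wind = 1,
                          rh = 50, regulate = FALSE, target = NULL,
                          config = thermo_config(), band_tolerance = 0.05) {
  rows <- purrr::map(temps, function(tc) {
    env <- list(t_air = tc, wind = wind, rh = rh, solar_flux = 0,
                t_sky = tc, t_ground = tc)
    if (!regulate) {
      bal <- whole_animal(geometry, env, params)
      tibble(t_chamber = tc, q_gen = bal$whole$q_gen)
    } else {
      reg <- regulate_hour(geometry, env, params,
                           state = regulation_state(params),
                           target = target, config = config,
                           band_tolerance = band_tolerance)
      tibble(t_chamber = tc, q_gen = reg$fluxes$q_gen,
             in_band = reg$in_band, panting = reg$state$panting,
             posture = reg$state$posture,
             k_flesh = reg$state$k_flesh, t_core = reg$state$t_core)
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bear_chamber", class(out))
  out
}
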