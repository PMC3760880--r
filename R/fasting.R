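# Seasonal fasting simulation.
#
# The fast is divided into intervals (default 4 days). For each interval
# one representative day is solved hourly through the thermoregulation
# cascade; the daily energetic demand times the interval length is drawn
# from the bear's energy stores, partitioned into fat and lean losses at
# the scenario's fat-energy fraction, and the body composition and part
# geometry are rebuilt before the next interval. A bear starves when its
# energy stores reach zero.

#' Partition an energetic demand into fat and lean mass losses
#'
#' Fat (39.3 MJ/kg) supplies fraction `f` of the demand and lean storage
#' mass (22% protein at 18.0 MJ/kg, i.e. 3.96 MJ/kg of lean mass) the
#' rest. If either pool cannot cover its share, the shortfall's energy is
#' drawn from the other pool at that pool's energy density; losses never
#' exceed availability, and any demand left when both pools empty is
#' returned as `unmet_mj`.
#'
#' @param demand_mj energetic demand, MJ (>= 0).
#' @param f fat-energy fraction in (0, 1].
#' @param fat_available,lean_available pool sizes, kg.
#' @return list: `fat_loss`, `lean_loss` (kg), `unmet_mj`.
#' @export
#' @examples
#' partition_energy(43.26, 0.9085, 100, 100)  # ~1 kg from each pool
partition_energy <- function(demand_mj, f, fat_available, lean_available) {
  stopifnot(demand_mj >= 0, f > 0, f <= 1)
  fat_loss <- f * demand_mj / .const$e_fat
  lean_loss <- (1 - f) * demand_mj / .const$e_lean
  if (lean_loss > lean_available) {
    shortfall <- (lean_loss - lean_available) * .const$e_lean
    lean_loss <- lean_available
    fat_loss <- fat_loss + shortfall / .const$e_fat
  }
  if (fat_loss > fat_available) {
    shortfall <- (fat_loss - fat_available) * .const$e_fat
    fat_loss <- fat_available
    extra_lean <- shortfall / .const$e_lean
    room <- lean_available - lean_loss
    lean_loss <- lean_loss + min(extra_lean, room)
    shortfall <- max(0, extra_lean - room) * .const$e_lean
  } else shortfall <- 0
  list(fat_loss = fat_loss, lean_loss = lean_loss, unmet_mj = shortfall)
}

# fur season for a date given the scenario's coat-switch month-day
coat_season <- function(date, winter_coat_date) {
  md <- format(as.Date(date), "%m-%d")
  if (md >= winter_coat_date | md < "03-01") "winter" else "summer"
}

#' Run a fasting simulation for one bear
#'
#' @param bear one-row composition tibble from [init_composition()].
#' @param climate daily climate tibble covering the scenario window (the
#'   scenario's `temp_offset` is applied here, to both extremes).
#' @param scenario [fast_scenario()] list.
#' @param params neutral [bear_params()] list.
#' @param config [thermo_config()] list.
#' @param keep_hours keep the hourly flux/state log (larger object).
#' @return An object of class `bear_fast`; see [tidy.bear_fast()] and
#'   [glance.bear_fast()].
#' @export
run_fast <- function(bear, climate, scenario = fast_scenario(),
                     params = bear_params(), config = thermo_config(),
                     keep_hours = FALSE) {
  dates <- scenario$start_date + seq_len(scenario$duration_days) - 1
  window <- climate[climate$date %in% dates, ]
  if (nrow(window) != length(dates))
    abort("climate does not cover the scenario window (climate gap)")
  window <- window[order(window$date), ]
  window$t_max <- window$t_max + scenario$temp_offset
  window$t_min <- window$t_min + scenario$temp_offset
  env_all <- hourly_microenv(window)

  n_int <- scenario$duration_days / scenario$interval_days
  f <- scenario$fat_energy_fraction
  fat <- bear$fat_mass; lean <- bear$lean_mass
  mass <- bear$total_mass
  energy <- energy_stores(fat, lean)
  state <- regulation_state(params)
  cum_loss <- 0
  avg_loss <- NA_real_
  avg_loss_frozen <- NA_real_
  survived <- TRUE
  survival_day <- scenario$duration_days
  intervals <- vector("list", n_int)
  hours_log <- if (keep_hours) vector("list", n_int) else NULL

  for (i in seq_len(n_int)) {
    day_off <- (i - 1) * scenario$interval_days +
      if (scenario$representative_day == "first") 1 else
        ceiling(scenario$interval_days / 2)
    rep_date <- dates[day_off]
    comp <- tibble(straight_length = bear$straight_length,
                   total_mass = mass, fat_mass = fat)
    season <- coat_season(rep_date, scenario$winter_coat_date)
    geometry <- build_geometry(comp, part_specs(season))
    target <- target_rate(mass, scenario$target_a, scenario$target_b)
    env_day <- env_all[env_all$date == rep_date, ]
    if (!config$carry_state) state <- regulation_state(params)
    q_h <- numeric(24); pant_h <- logical(24); unres_h <- logical(24)
    curled_h <- logical(24); shade_h <- logical(24)
    for (h in 1:24) {
      reg <- regulate_hour(geometry, as.list(env_day[h, ]), params, state,
                           target = target, config = config,
                           band_tolerance = scenario$band_tolerance,
                           shade_available = scenario$shade_available)
      state <- reg$state
      q <- reg$fluxes$q_gen
      if (config$panting_surcharge > 0 && state$panting)
        q <- q * (1 + config$panting_surcharge)
      q_h[h] <- q
      pant_h[h] <- state$panting
      unres_h[h] <- state$unresolvable
      curled_h[h] <- state$posture == "curled"
      shade_h[h] <- state$shade_on
    }
    daily_mj <- sum(q_h) * 3600 / 1e6
    interval_mj <- daily_mj * scenario$interval_days
    had_both <- fat > 1e-9 && lean > 1e-9

    if (interval_mj >= energy) {
      # starvation mid-interval: pro-rata day count at this interval's rate
      extra_days <- floor(energy / max(daily_mj, 1e-12))
      survival_day <- (i - 1) * scenario$interval_days + extra_days
      survived <- FALSE
      pe <- partition_energy(energy, f, fat, lean)
      cum_loss <- cum_loss + pe$fat_loss + pe$lean_loss
      fat <- fat - pe$fat_loss; lean <- lean - pe$lean_loss
      mass <- mass - pe$fat_loss - pe$lean_loss
      energy <- 0
    } else {
      pe <- partition_energy(interval_mj, f, fat, lean)
      cum_loss <- cum_loss + pe$fat_loss + pe$lean_loss
      fat <- fat - pe$fat_loss; lean <- lean - pe$lean_loss
      mass <- mass - pe$fat_loss - pe$lean_loss
      energy <- energy - interval_mj
    }
    days_elapsed <- min(i * scenario$interval_days, survival_day)
    avg_loss <- cum_loss / max(days_elapsed, 1)
    if (had_both) avg_loss_frozen <- avg_loss

    intervals[[i]] <- tibble(
      interval = i, date = rep_date, season = season,
      total_mass = mass, fat_mass = fat, lean_mass = lean,
      energy_mj = energy, daily_demand_mj = daily_mj,
      target_w = target,
      mean_rate_w = daily_mj * 1e6 / 86400,
      panting_hours = sum(pant_h), unresolvable_hours = sum(unres_h),
      curled_hours = sum(curled_h), shade_hours = sum(shade_h),
      elevated_demand = daily_mj * 1e6 / 86400 > 1.05 * target,
      avg_daily_loss_kg = avg_loss)
    if (keep_hours)
      hours_log[[i]] <- dplyr::mutate(env_day, q_gen = q_h, panting = pant_h,
                                      unresolvable = unres_h,
                                      curled = curled_h, shade = shade_h,
                                      interval = i)
    if (!survived) break
  }
  iv <- dplyr::bind_rows(intervals)
  total_hours <- 24 * nrow(iv)
  structure(list(
    intervals = iv,
    bear = bear, scenario = scenario,
    survived = survived, survival_day = survival_day,
    avg_daily_weight_loss = if (is.na(avg_loss_frozen)) avg_loss else avg_loss_frozen,
    pct_energy_remaining = 100 * energy / bear$energy_mj,
    panting_hour_fraction = sum(iv$panting_hours) / total_hours,
    unresolvable_hour_fraction = sum(iv$unresolvable_hours) / total_hours,
    elevated_demand_days = sum(iv$elevated_demand),
    hours = if (keep_hours) dplyr::bind_rows(hours_log) else NULL),
    class = "bear_fast")
}

#' Run the fast for every bear in a population
#'
#' @param population composition tibble (e.g. [generate_population()]).
#' @inheritParams run_fast
#' @return A tibble with one summary row per bear ([glance.bear_fast()]
#'   columns bound to the composition columns).
#' @export
run_fast_population <- function(population, climate,
                                scenario = fast_scenario(),
                                params = bear_params(),
                                config = thermo_config()) {
  purrr::map_dfr(seq_len(nrow(population)), function(i) {
    bear <- population[i, ]
    dplyr::bind_cols(
      bear[, intersect(c("straight_length", "sex", "condition",
                         "condition_multiplier"), names(bear))],
      glance(run_fast(bear, climate, scenario, params, config)))
  })
}

#' Minimum energy density for survival
#'
#' Sweeps initial size from 1.1 x structural mass upward in steps of 0.1 x
#' structural mass until the first size survives the scenario's fast, and
#' fits an ordinary least-squares line of survived fraction of the fast
#' against initial energy density (total energy stores / lean body mass,
#' MJ/kg). The reported minimum density is where the fitted line reaches
#' full survival.
#'
#' @param length straight-line body length, m (2.30 and 2.00 m are the
#'   male/female population proxies).
#' @param sex `"male"` or `"female"`.
#' @param climate daily climate tibble.
#' @param scenario [fast_scenario()] list.
#' @param multiplier_start,multiplier_step,multiplier_cap sweep range of
#'   the condition multiplier.
#' @param params,config solver settings passed to [run_fast()].
#' @return An object of class `bear_med` with the sweep table, the fitted
#'   line, the minimum energy density (MJ/kg) and a `flag` that is
#'   `"ok"`, `"lower_bound"` (every size survived) or `"no_survivor"`.
#' @export
minimum_energy_density <- function(length, sex, climate,
                                   scenario = fast_scenario(),
                                   multiplier_start = 1.1,
                                   multiplier_step = 0.1,
                                   multiplier_cap = 3.5,
                                   params = bear_params(),
                                   config = thermo_config()) {
  mult <- multiplier_start
  rows <- list()
  repeat {
    bear <- init_composition(length, mult, sex)
    res <- run_fast(bear, climate, scenario, params, config)
    density <- bear$energy_mj / (bear$total_mass - bear$fat_mass)
    rows[[length(rows) + 1]] <- tibble(
      condition_multiplier = mult, energy_density = density,
      survived = res$survived,
      fraction_survived = res$survival_day / scenario$duration_days)
    if (res$survived || mult >= multiplier_cap) break
    mult <- mult + multiplier_step
  }
  sweep <- dplyr::bind_rows(rows)
  fitted <- fit_min_density(sweep)
  flag <- fitted$flag
  fit <- fitted$fit
  min_density <- fitted$min_density
  structure(list(sweep = sweep, fit = fit, min_density = min_density,
                 flag = flag, length = length, sex = sex,
                 scenario = scenario),
            class = "bear_med")
}

# ordinary least squares of survived fraction on initial energy density;
# the minimum density is where the fitted line reaches full survival
fit_min_density <- function(sweep) {
  flag <- if (sweep$survived[1]) "lower_bound" else
    if (!any(sweep$survived)) "no_survivor" else "ok"
  if (flag == "lower_bound")
    return(list(fit = NULL, min_density = sweep$energy_density[1], flag = flag))
  if (flag == "no_survivor")
    return(list(fit = NULL, min_density = NA_real_, flag = flag))
  fit <- lm(fraction_survived ~ energy_density, data = sweep)
  list(fit = fit,
       min_density = unname((1 - coef(fit)[1]) / coef(fit)[2]),
       flag = flag)
}
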