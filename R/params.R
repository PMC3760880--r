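#' Biophysical parameter set
#'
#' Bundles the thermal and physiological parameters of the heat-balance
#' model. Defaults follow the published property values for polar bears:
#' core temperature 37 degC (bounds 36-39), flesh thermal conductivity
#' within 0.4-2.8 W/m.degC, still-air fur conductivity 0.0628 W/m.degC
#' increasing linearly by 7% per m/s of wind up to 7 m/s, hair solar
#' reflectivity 0.61, and oxygen extraction efficiency 20% (bounds 5-20%).
#'
#' @param t_core core body temperature, degC.
#' @param t_core_min,t_core_max bounds for thermoregulatory core swings, degC.
#' @param k_flesh flesh (vasomotor) thermal conductivity, W/m.degC.
#' @param k_flesh_min,k_flesh_max vasoconstriction/vasodilation bounds.
#' @param k_fat subcutaneous fat (blubber) conductivity, W/m.degC.
#' @param k_fur_still still-air fur thermal conductivity, W/m.degC.
#' @param fur_wind_gain fractional conductivity increase per m/s wind.
#' @param fur_wind_cap wind speed (m/s) beyond which the gain saturates.
#' @param hair_reflectivity solar reflectivity of the coat (0-1).
#' @param emissivity longwave emissivity of fur and environment surfaces.
#' @param o2_extraction oxygen extraction efficiency (fraction).
#' @param o2_extraction_min floor reached by panting.
#' @param skin_wet_fraction baseline wetted skin fraction for cutaneous
#'   evaporation; sweating is disabled for bears, so this stays fixed.
#' @param e_per_l_o2 metabolic energy yield per litre of O2, J/L.
#'
#' @return A list of class `bear_params`.
#' @export
#' @examples
#' p <- bear_params()
#' p$k_fur_still
bear_params <- function(t_core = 37, t_core_min = 36, t_core_max = 39,
                        k_flesh = 1.0, k_flesh_min = 0.4, k_flesh_max = 2.8,
                        k_fat = 0.20,
                        k_fur_still = 0.0628, fur_wind_gain = 0.07,
                        fur_wind_cap = 7,
                        hair_reflectivity = 0.61, emissivity = 0.95,
                        o2_extraction = 0.20, o2_extraction_min = 0.05,
                        skin_wet_fraction = 0.005,
                        e_per_l_o2 = 20100) {
  stopifnot(t_core >= t_core_min, t_core <= t_core_max)
  if (k_flesh < k_flesh_min || k_flesh > k_flesh_max)
    abort("k_flesh outside its physiological bounds")
  if (o2_extraction < o2_extraction_min || o2_extraction > 0.20)
    abort("o2_extraction outside 5-20% bounds")
  structure(
    list(t_core = t_core, t_core_min = t_core_min, t_core_max = t_core_max,
         k_flesh = k_flesh, k_flesh_min = k_flesh_min, k_flesh_max = k_flesh_max,
         k_fat = k_fat, k_fur_still = k_fur_still,
         fur_wind_gain = fur_wind_gain, fur_wind_cap = fur_wind_cap,
         hair_reflectivity = hair_reflectivity, emissivity = emissivity,
         o2_extraction = o2_extraction, o2_extraction_min = o2_extraction_min,
         skin_wet_fraction = skin_wet_fraction, e_per_l_o2 = e_per_l_o2),
    class = "bear_params")
}

#' Default body-part proportion table
#'
#' Relative body-part dimensions measured on photographs, in arbitrary photo
#' units; the head + neck + torso lengths sum to 11.5 units so that a 2.30 m
#' bear uses a scaling factor of 20 cm per unit. The neck, torso and legs are
#' cylinders; the head is a truncated cone with muzzle/base radius ratio
#' `taper`. Fur depths are the published per-part sets (mm): summer
#' 10/20/20/20 and winter 15/45/60/35 for head/neck/torso/legs, plus a
#' "reference" set 10/40/50/35 used for geometric validation. The table was
#' calibrated once so whole-bear skin and fur areas of average-condition
#' bears track the live-bear allometric equations (see
#' [validate_allometry()]); it can be replaced wholesale by the user.
#'
#' @param season one of `"summer"`, `"winter"`, `"reference"`; selects which
#'   fur-depth column is copied into `fur_depth` (m).
#' @return A tibble with one row per part (legs appear as one row per pair
#'   with `count = 2`).
#' @export
part_specs <- function(season = c("reference", "summer", "winter")) {
  season <- match.arg(season)
  fur <- switch(season,
    summer    = c(head = 10, neck = 20, torso = 20, front_leg = 20, hind_leg = 20),
    winter    = c(head = 15, neck = 45, torso = 60, front_leg = 35, hind_leg = 35),
    reference = c(head = 10, neck = 40, torso = 50, front_leg = 35, hind_leg = 35))
  tibble(
    part        = c("head", "neck", "torso", "front_leg", "hind_leg"),
    shape       = c("truncated_cone", "cylinder", "cylinder", "cylinder", "cylinder"),
    photo_length = c(2.0, 1.5, 8.0, 3.8, 3.8),
    photo_diam   = c(1.6, 2.0, 3.1, 1.1, 1.2),
    count       = c(1L, 1L, 1L, 2L, 2L),
    taper       = c(0.6, NA, NA, NA, NA),
    fur_depth   = unname(fur[c("head", "neck", "torso", "front_leg", "hind_leg")]) / 1000,
    season      = season)
}

#' Fasting-target metabolic rate
#'
#' The mass-specific maintenance rate targeted during the fast,
#' `a * mass^b` watts with the default `a = 2.66` and `b = 0.78`
#' (the 55 kcal/day/kg^0.78 field energy requirement converted to watts).
#'
#' @param mass total body mass, kg.
#' @param a,b allometric coefficient (W/kg^b) and exponent.
#' @return Target metabolic rate, W.
#' @export
#' @examples
#' target_rate(400)
target_rate <- function(mass, a = 2.66, b = 0.78) {
  stopifnot(all(mass > 0))
  a * mass^b
}

#' Fast scenario definition
#'
#' @param start_date fast start (`Date` or ISO string); July 29 and June 11
#'   are the historical and extended-fast defaults explored in the package.
#' @param duration_days fast length (must be divisible by `interval_days`).
#' @param interval_days body-composition update interval (default 4 days).
#' @param sim which fat-use scenario: 1, 2 or 3, fixing the fraction of
#'   energetic demand supplied by fat at 94.66%, 90.85% or 88.56%; or use
#'   `fat_energy_fraction` directly.
#' @param fat_energy_fraction explicit fat fraction in (0, 1]; overrides `sim`.
#' @param shade_available can the bear seek full shade when hot?
#' @param temp_offset uniform offset (degC) added to daily max/min air
#'   temperature (e.g. 3 for the warmed-climate scenario).
#' @param band_tolerance half-width of the accepted metabolic band
#'   (fraction of target; default 0.05).
#' @param target_a,target_b target-rate allometry passed to [target_rate()].
#' @param winter_coat_date month-day (`"mm-dd"`) on which fur switches from
#'   the summer to the winter depth set.
#' @param representative_day which day of each interval drives the heat
#'   balance (`"first"` or `"mid"`).
#' @return A list of class `fast_scenario`.
#' @export
fast_scenario <- function(start_date = "2000-07-29", duration_days = 120,
                          interval_days = 4, sim = 2,
                          fat_energy_fraction = NULL,
                          shade_available = FALSE, temp_offset = 0,
                          band_tolerance = 0.05,
                          target_a = 2.66, target_b = 0.78,
                          winter_coat_date = "10-01",
                          representative_day = c("first", "mid")) {
  f <- fat_energy_fraction %||% c(0.9466, 0.9085, 0.8856)[sim]
  if (f <= 0 || f > 1) abort("fat_energy_fraction must lie in (0, 1]")
  if (duration_days %% interval_days != 0)
    abort("duration_days must be divisible by interval_days")
  structure(
    list(start_date = as.Date(start_date), duration_days = duration_days,
         interval_days = interval_days, fat_energy_fraction = f,
         shade_available = shade_available, temp_offset = temp_offset,
         band_tolerance = band_tolerance,
         target_a = target_a, target_b = target_b,
         winter_coat_date = winter_coat_date,
         representative_day = match.arg(representative_day)),
    class = "fast_scenario")
}

#' Thermoregulation cascade settings
#'
#' Increment sizes and options for the thermoregulatory cascade. Bounds come
#' from the physiological parameter set; increments are model choices.
#'
#' @param k_flesh_step vasomotor conductivity step, W/m.degC.
#' @param t_core_step core-temperature step, degC.
#' @param o2_step oxygen-extraction (panting) step, fraction.
#' @param allow_curl allow curled posture when cold.
#' @param panting_surcharge fractional metabolic surcharge while panting
#'   (default 0: panting is energetically free).
#' @param carry_state start each hour from the previous hour's regulation
#'   state (`TRUE`) or re-solve from neutral (`FALSE`).
#' @return A list of class `thermo_config`.
#' @export
thermo_config <- function(k_flesh_step = 0.2, t_core_step = 0.5,
                          o2_step = 0.025, allow_curl = TRUE,
                          panting_surcharge = 0, carry_state = TRUE) {
  structure(list(k_flesh_step = k_flesh_step, t_core_step = t_core_step,
                 o2_step = o2_step, allow_curl = allow_curl,
                 panting_surcharge = panting_surcharge,
                 carry_state = carry_state),
            class = "thermo_config")
}
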