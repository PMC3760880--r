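# Hierarchical thermoregulation.
#
# When the solved metabolic rate leaves the accepted band around the
# target rate, options are engaged in a fixed order -- behavioral first,
# then physiological:
#   cold side: curled posture -> vasoconstriction (flesh conductivity down)
#              -> core temperature down
#   hot side:  shade (if available) -> vasodilation (flesh conductivity up)
#              -> core temperature up -> panting (oxygen extraction down)
# Sweating is never engaged for bears. Each increment re-solves the heat
# balance; the first state whose rate lands in the band is kept, and if the
# options are exhausted the closest achievable rate is returned with the
# unresolvable flag set.

#' Neutral thermoregulation state
#'
#' @param params [bear_params()] list supplying the neutral values.
#' @return list of class `regulation_state` with `posture`, `shade_on`,
#'   `k_flesh`, `t_core`, `o2_extraction`, `panting`, `unresolvable`.
#' @export
regulation_state <- function(params = bear_params()) {
  structure(list(posture = "uncurled", shade_on = FALSE,
                 k_flesh = params$k_flesh, t_core = params$t_core,
                 o2_extraction = params$o2_extraction,
                 panting = FALSE, unresolvable = FALSE,
                 locked = character()),
            class = "regulation_state")
}

# apply a regulation state onto the neutral parameter set
apply_state <- function(params, state) {
  params$k_flesh <- state$k_flesh
  params$t_core <- state$t_core
  params$o2_extraction <- state$o2_extraction
  params
}

solve_state <- function(geometry, env, params, state, rf_init = 0) {
  whole_animal_list(geometry_parts(geometry), env, apply_state(params, state),
                    posture = state$posture,
                    shade = if (state$shade_on) 1 else 0,
                    rf_init = rf_init)
}

# one relaxation step toward neutral, reverse cascade order; returns NULL
# when already neutral
relax_one <- function(state, params, config) {
  s <- state
  if (s$o2_extraction < params$o2_extraction - 1e-12) {
    s$o2_extraction <- min(params$o2_extraction, s$o2_extraction + config$o2_step)
    return(s)
  }
  if (abs(s$t_core - params$t_core) > 1e-12) {
    s$t_core <- s$t_core + sign(params$t_core - s$t_core) *
      min(config$t_core_step, abs(params$t_core - s$t_core))
    return(s)
  }
  if (abs(s$k_flesh - params$k_flesh) > 1e-12) {
    s$k_flesh <- s$k_flesh + sign(params$k_flesh - s$k_flesh) *
      min(config$k_flesh_step, abs(params$k_flesh - s$k_flesh))
    return(s)
  }
  if (s$shade_on) { s$shade_on <- FALSE; return(s) }
  if (s$posture == "curled") { s$posture <- "uncurled"; return(s) }
  NULL
}

# next cascade increment on the cold or hot side; returns the candidate
# state plus which field moved (for within-step refinement), or NULL when
# the side's options are exhausted. `locked` names binary options that
# already toggled this hour and may not toggle back.
engage_one <- function(state, params, config, side, shade_available,
                       locked = character()) {
  s <- state
  if (side == "cold") {
    # undo any leftover hot-side options before engaging cold ones
    if (s$o2_extraction < params$o2_extraction - 1e-12) {
      s$o2_extraction <- min(params$o2_extraction,
                             s$o2_extraction + config$o2_step)
      return(list(state = s, field = "o2_extraction", binary = FALSE))
    }
    if (s$shade_on && !"shade" %in% locked) {
      s$shade_on <- FALSE
      return(list(state = s, field = "shade", binary = TRUE))
    }
    if (config$allow_curl && s$posture == "uncurled" && !"posture" %in% locked) {
      s$posture <- "curled"
      return(list(state = s, field = "posture", binary = TRUE))
    }
    if (s$k_flesh > params$k_flesh_min + 1e-12 && !"k_flesh" %in% locked) {
      s$k_flesh <- max(params$k_flesh_min, s$k_flesh - config$k_flesh_step)
      return(list(state = s, field = "k_flesh", binary = FALSE))
    }
    if (s$t_core > params$t_core_min + 1e-12 && !"t_core" %in% locked) {
      s$t_core <- max(params$t_core_min, s$t_core - config$t_core_step)
      return(list(state = s, field = "t_core", binary = FALSE))
    }
  } else {
    if (s$posture == "curled" && !"posture" %in% locked) {
      s$posture <- "uncurled"
      return(list(state = s, field = "posture", binary = TRUE))
    }
    if (shade_available && !s$shade_on && !"shade" %in% locked) {
      s$shade_on <- TRUE
      return(list(state = s, field = "shade", binary = TRUE))
    }
    if (s$k_flesh < params$k_flesh_max - 1e-12 && !"k_flesh" %in% locked) {
      s$k_flesh <- min(params$k_flesh_max, s$k_flesh + config$k_flesh_step)
      return(list(state = s, field = "k_flesh", binary = FALSE))
    }
    if (s$t_core < params$t_core_max - 1e-12 && !"t_core" %in% locked) {
      s$t_core <- min(params$t_core_max, s$t_core + config$t_core_step)
      return(list(state = s, field = "t_core", binary = FALSE))
    }
    # sweating would come next but is disabled for bears; panting is last
    if (s$o2_extraction > params$o2_extraction_min + 1e-12 &&
        !"o2_extraction" %in% locked) {
      s$o2_extraction <- max(params$o2_extraction_min,
                             s$o2_extraction - config$o2_step)
      return(list(state = s, field = "o2_extraction", binary = FALSE))
    }
  }
  NULL
}

# the panting flag is simply "oxygen extraction below neutral"
sync_panting <- function(state, params, locked = character()) {
  state$panting <- state$o2_extraction < params$o2_extraction - 1e-12
  state$locked <- locked
  state
}

# a continuous control stepped across the band: bisect the control between
# its previous and candidate values until the solved rate lands in band
refine_control <- function(geometry, env, params, state, field, v_prev, v_new,
                           lo, hi, side, rf_init, max_iter = 40) {
  a <- v_prev; b <- v_new
  for (i in seq_len(max_iter)) {
    mid <- (a + b) / 2
    s <- state
    s[[field]] <- mid
    bal <- solve_state(geometry, env, params, s, rf_init)
    if (bal$q_gen >= lo && bal$q_gen <= hi)
      return(list(state = s, bal = bal))
    # still on the starting side of the band -> move toward the candidate,
    # otherwise we stepped across it -> pull back toward the previous value
    still_short <- if (side == "cold") bal$q_gen > hi else bal$q_gen < lo
    if (still_short) a <- mid else b <- mid
    if (abs(b - a) < 1e-9) break
  }
  NULL
}

#' Regulate one hour to the target metabolic band
#'
#' Solves the heat balance, and if the metabolic rate is outside
#' `target * (1 +/- band_tolerance)` walks the thermoregulatory cascade one
#' increment at a time until the rate enters the band or options run out.
#' With `carry_state` the hour starts from the previous hour's state and
#' first relaxes toward neutral while that keeps the rate in band.
#'
#' @param geometry parts tibble from [build_geometry()].
#' @param env microenvironment row.
#' @param params neutral [bear_params()] list.
#' @param state starting [regulation_state()].
#' @param target target metabolic rate, W.
#' @param config [thermo_config()] list.
#' @param band_tolerance accepted fractional deviation (default 0.05).
#' @param shade_available may the bear seek full shade?
#' @return list: `fluxes` (whole-animal flux row), `state` (final
#'   regulation state), `in_band`, `parts`.
#' @export
regulate_hour <- function(geometry, env, params, state = regulation_state(params),
                          target, config = thermo_config(),
                          band_tolerance = 0.05, shade_available = FALSE) {
  lo <- target * (1 - band_tolerance)
  hi <- target * (1 + band_tolerance)
  state$unresolvable <- FALSE
  state$locked <- character()   # locks live for one hour only
  env <- as.list(env)
  geometry <- geometry_parts(geometry)
  bal <- solve_state(geometry, env, params, state)
  q <- bal$q_gen

  if (q >= lo && q <= hi && config$carry_state) {
    # relax engaged options one step at a time while staying in band
    repeat {
      cand <- relax_one(state, params, config)
      if (is.null(cand)) break
      cbal <- solve_state(geometry, env, params, cand, bal$resp_fraction)
      cq <- cbal$q_gen
      if (cq >= lo && cq <= hi) {
        state <- cand; bal <- cbal; q <- cq
      } else break
    }
    tb <- balance_as_tibbles(bal)
    return(list(fluxes = tb$whole, state = sync_panting(state, params),
                in_band = TRUE, parts = tb$parts))
  }
  if (q >= lo && q <= hi) {
    tb <- balance_as_tibbles(bal)
    return(list(fluxes = tb$whole, state = state, in_band = TRUE,
                parts = tb$parts))
  }

  best <- list(state = state, bal = bal, dist = abs(q - target))
  locked <- character()
  skipped <- character()
  for (step in 1:200) {
    side <- if (q > hi) "cold" else "hot"
    cand <- engage_one(state, params, config, side, shade_available, locked)
    if (is.null(cand)) {
      if (length(skipped) == 0) break
      # the continuous controls ran out without reaching the band: take the
      # binary option that was skipped for overshooting and keep walking
      # (the side flips; the binary stays locked so it cannot toggle back)
      fld <- skipped[1]
      skipped <- skipped[-1]
      if (fld == "posture")
        state$posture <- if (state$posture == "curled") "uncurled" else "curled"
      else state$shade_on <- !state$shade_on
      bal <- solve_state(geometry, env, params, state, bal$resp_fraction)
      q <- bal$q_gen
      if (q >= lo && q <= hi) {
        tb <- balance_as_tibbles(bal)
        return(list(fluxes = tb$whole,
                    state = sync_panting(state, params, locked),
                    in_band = TRUE, parts = tb$parts))
      }
      if (abs(q - target) < best$dist)
        best <- list(state = state, bal = bal, dist = abs(q - target))
      next
    }
    cbal <- solve_state(geometry, env, params, cand$state, bal$resp_fraction)
    cq <- cbal$q_gen
    if (cq >= lo && cq <= hi) {
      tb <- balance_as_tibbles(cbal)
      return(list(fluxes = tb$whole,
                  state = sync_panting(cand$state, params, locked),
                  in_band = TRUE, parts = tb$parts))
    }
    crossed <- if (side == "cold") cq < lo else cq > hi
    if (crossed && !cand$binary) {
      # a continuous control stepped over the band: refine within the step
      ref <- refine_control(geometry, env, params, state, cand$field,
                            state[[cand$field]], cand$state[[cand$field]],
                            lo, hi, side, bal$resp_fraction)
      if (!is.null(ref)) {
        tb <- balance_as_tibbles(ref$bal)
        return(list(fluxes = tb$whole,
                    state = sync_panting(ref$state, params, locked),
                    in_band = TRUE, parts = tb$parts))
      }
    }
    if (crossed && cand$binary) {
      # a posture/shade toggle would jump the band: hold it back, keep the
      # current posture, and let the finer physiological controls work
      locked <- c(locked, cand$field)
      skipped <- c(skipped, cand$field)
      next
    }
    if (!crossed && abs(cq - target) > abs(q - target) + 1e-9) {
      # the option moved the rate away from the target (e.g. vasodilation
      # when the environment is hotter than the core): revert and lock it
      locked <- c(locked, cand$field)
      next
    }
    state <- cand$state
    bal <- cbal
    q <- cq
    if (abs(cq - target) < best$dist)
      best <- list(state = state, bal = cbal, dist = abs(cq - target))
  }
  st <- sync_panting(best$state, params, locked)
  st$unresolvable <- TRUE
  tb <- balance_as_tibbles(best$bal)
  list(fluxes = tb$whole, state = st, in_band = FALSE,
       parts = tb$parts)
}
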