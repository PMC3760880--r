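# Hierarchical thermoregulation cascade.

test_that("target rate follows the fasting allometry", {
  expect_equal(target_rate(1), 2.66)
  expect_equal(target_rate(400), 2.66 * 400^0.78)
  expect_lt(abs(target_rate(400) - 285), 1)
  # the kcal/day field equation converts to the same coefficient
  expect_equal(round(55 * 4184 / 86400, 2), 2.66)
})

test_that("a rate already in band leaves the neutral state untouched", {
  p <- bear_params()
  g <- fixture_geometry("summer")
  env <- chamber_env(0, wind = 4)
  q0 <- whole_animal(g, env, p)$whole$q_gen
  reg <- regulate_hour(g, env, p, target = q0, config = thermo_config())
  expect_true(reg$in_band)
  expect_equal(reg$state$k_flesh, p$k_flesh)
  expect_equal(reg$state$t_core, p$t_core)
  expect_equal(reg$state$posture, "uncurled")
  expect_false(reg$state$panting)
})

test_that("shade is engaged before any physiological option when hot", {
  p <- bear_params()
  g <- fixture_geometry("summer")
  env <- outdoor_env(18, wind = 2, solar = 700, t_ground = 25, t_sky = 5)
  target <- target_rate(409)
  q0 <- whole_animal(g, env, p)$whole$q_gen
  expect_lt(q0, 0.95 * target)   # hot: solved rate below band
  reg <- regulate_hour(g, env, p, target = target, shade_available = TRUE)
  expect_true(reg$state$shade_on)
  # shade fully removes the solar load
  expect_equal(reg$fluxes$q_sol, 0)
})

test_that("panting only engages after vasodilation and heat storage max out", {
  p <- bear_params()
  g <- fixture_geometry("summer")
  for (t in c(22, 26, 30)) {
    env <- outdoor_env(t, wind = 1, solar = 650, t_ground = t + 5,
                       t_sky = t - 12)
    reg <- regulate_hour(g, env, p, target = target_rate(409))
    # earlier cascade steps must have no useful headroom left: either the
    # control saturated or it was locked as counterproductive this hour
    spent <- function(field, at_bound)
      at_bound || field %in% reg$state$locked
    if (reg$state$panting) {
      expect_true(spent("k_flesh", reg$state$k_flesh == p$k_flesh_max))
      expect_true(spent("t_core", reg$state$t_core == p$t_core_max))
    }
    if (reg$state$t_core > p$t_core)
      expect_true(spent("k_flesh", reg$state$k_flesh == p$k_flesh_max))
  }
})

test_that("cold-side heat storage only draws down after full vasoconstriction", {
  p <- bear_params()
  g <- fixture_geometry("summer")
  for (t in c(-5, -15, -30)) {
    reg <- regulate_hour(g, chamber_env(t, wind = 6), p,
                         target = target_rate(409))
    if (reg$state$t_core < p$t_core)
      expect_equal(reg$state$k_flesh, p$k_flesh_min)
  }
})

test_that("regulation never moves the rate away from the target", {
  p <- bear_params()
  g <- fixture_geometry("winter")
  target <- target_rate(409)
  for (t in c(-35, -20, -5, 5, 15, 25)) {
    env <- chamber_env(t, wind = 3)
    q0 <- whole_animal(g, env, p)$whole$q_gen
    reg <- regulate_hour(g, env, p, target = target)
    expect_lte(abs(reg$fluxes$q_gen - target), abs(q0 - target) + 1e-9)
  }
})

test_that("exhausted options set the unresolvable flag at the closest rate", {
  p <- bear_params()
  g <- fixture_geometry("winter")   # heavy coat in severe heat
  env <- outdoor_env(24, wind = 0.5, solar = 700, t_ground = 30, t_sky = 14)
  target <- target_rate(409)
  reg <- regulate_hour(g, env, p, target = target, shade_available = FALSE)
  expect_false(reg$in_band)
  expect_true(reg$state$unresolvable)
  expect_lt(reg$fluxes$q_gen, 0.95 * target)
  expect_true(reg$state$panting)
  expect_equal(reg$state$o2_extraction, p$o2_extraction_min)
})

test_that("carried state relaxes back toward neutral when unneeded", {
  p <- bear_params()
  g <- fixture_geometry("winter")
  target <- target_rate(409)
  cold <- regulate_hour(g, chamber_env(-25, wind = 6), p, target = target)
  expect_lt(cold$state$k_flesh, p$k_flesh)
  # hand the cold-adapted state to a mild hour: regulation backs off
  mild <- regulate_hour(g, chamber_env(5, wind = 2), p, state = cold$state,
                        target = target)
  expect_gte(mild$state$k_flesh, cold$state$k_flesh)
})

test_that("re-solving from neutral is available as a configuration", {
  p <- bear_params()
  g <- fixture_geometry("summer")
  cfg <- thermo_config(carry_state = FALSE)
  expect_false(cfg$carry_state)
  reg <- regulate_hour(g, chamber_env(0, wind = 4), p,
                       state = regulation_state(p),
                       target = target_rate(409), config = cfg)
  expect_true(is.list(reg$state))
})
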