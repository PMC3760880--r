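# Body composition, photo-scaled geometry, fat allocation, surface areas.

test_that("photo scaling factor reproduces the worked example and is linear", {
  specs <- part_specs()
  expect_equal(sum(specs$photo_length[specs$part %in% c("head", "neck", "torso")]),
               11.5)
  expect_equal(scaling_factor(specs, 2.30), 20)
  expect_equal(scaling_factor(specs, 0.115), 1)  # photo sum equals target
  expect_equal(scaling_factor(specs, 4.60), 2 * scaling_factor(specs, 2.30))
  expect_error(scaling_factor(specs, -1), "positive")
})

test_that("initial compositions reproduce the published anchor table", {
  # the 2.00 m poor female worked example: 1.5 x 120 kg structural
  b <- init_composition(2.00, 1.5, "female")
  expect_equal(b$total_mass, 180)
  expect_lt(abs(b$total_mass - 179), 1.5)       # printed table rounds
  # energy formula at the printed average-condition composition
  expect_equal(energy_stores(94, 56), 39.3 * 94 + 3.96 * 56)
  expect_lt(abs(energy_stores(94, 56) - 3905) / 3905, 0.005)
  expect_equal(energy_stores(0, 0), 0)
  # every anchor row is reproduced within table rounding
  anchors <- composition_anchors()
  mult <- c(poor = 1.5, average = 2.25, excellent = 3.0)
  for (i in seq_len(nrow(anchors))) {
    row <- anchors[i, ]
    b <- init_composition(row$length, mult[[row$condition]], row$sex)
    # printed totals are rounded from rounded structural masses (3 x 95
    # prints as 283): allow the compounded rounding
    expect_lt(abs(b$total_mass - row$total), 2.5)
    expect_lt(abs(b$fat_mass - row$fat), 2)
    expect_lt(abs(b$lean_mass - row$lean), 2)
    expect_lt(abs(b$energy_mj - row$energy) / row$energy, 0.02)
  }
})

test_that("structural mass interpolates anchors and extends smoothly", {
  anchors <- composition_anchors()
  for (i in seq_len(nrow(anchors)))
    expect_equal(structural_mass(anchors$length[i]), anchors$structural[i])
  lens <- seq(1.7, 2.6, by = 0.05)
  expect_true(all(diff(structural_mass(lens)) > 0))
  expect_equal(structural_mass(2.0, fn = function(l) 14 * l^3), 112)
})

test_that("population has 18 bears satisfying the composition identity", {
  pop <- generate_population()
  expect_equal(nrow(pop), 18)
  expect_equal(pop$total_mass,
               pop$structural_mass + pop$fat_mass + pop$lean_mass)
  ex245 <- pop[pop$straight_length == 2.45 & pop$condition == "excellent", ]
  expect_lte(abs(ex245$total_mass - 659), 1)
  expect_equal(pop$energy_mj, energy_stores(pop$fat_mass, pop$lean_mass))
})

test_that("energy stores are exactly linear in the two pools", {
  f <- c(10, 47.3); l <- c(5, 21.8)
  expect_equal(energy_stores(sum(f), sum(l)),
               sum(energy_stores(f, l)))
})

test_that("geometry hits the density target and conserves mass and fat", {
  for (mult in c(1.5, 2.25, 3.0)) {
    comp <- init_composition(2.30, mult, "male")
    g <- build_geometry(comp, part_specs("reference"))
    dens <- comp$total_mass / sum(pi * ifelse(
      g$shape == "truncated_cone",
      g$length / 3 * ((g$taper * g$skin_radius)^2 +
                        g$taper * g$skin_radius^2 + g$skin_radius^2),
      g$skin_radius^2 * g$length) * g$count)
    expect_gt(dens, 990); expect_lt(dens, 1010)
    expect_equal(sum(g$mass), comp$total_mass, tolerance = 1e-9)
    expect_equal(sum(g$fat_mass), 0.75 * comp$fat_mass, tolerance = 1e-9)
    expect_equal(g$fat_thickness[g$part == "head"], 0)
  }
})

test_that("same-length bears share part lengths but not diameters", {
  g1 <- build_geometry(init_composition(2.0, 1.5, "female"), part_specs())
  g2 <- build_geometry(init_composition(2.0, 3.0, "female"), part_specs())
  expect_equal(g1$length, g2$length)
  expect_true(all(g2$skin_radius > g1$skin_radius))
})

test_that("a fatless bear has no subcutaneous layer anywhere", {
  comp <- init_composition(2.0, 1.0, "female")   # storage mass zero
  g <- build_geometry(comp, part_specs())
  expect_equal(g$fat_thickness, rep(0, nrow(g)))
  expect_equal(g$flesh_radius, g$skin_radius)
})

test_that("fat annulus thickness matches the closed-form solution", {
  parts <- tibble::tibble(
    part = "cyl", shape = "cylinder", count = 1L, taper = NA_real_,
    length = 1, skin_radius = 0.3, volume = pi * 0.09)
  comp <- list(fat_mass = 0.01 * 901 / 0.75)  # 0.01 m^3 subcutaneous
  out <- allocate_fat(comp, parts)
  expect_equal(out$fat_thickness, 0.3 - sqrt(0.09 - 0.01 / pi),
               tolerance = 1e-10)
  # infeasible fat volume names the part
  comp_bad <- list(fat_mass = pi * 0.09 * 901 / 0.75 * 1.1)
  expect_error(allocate_fat(comp_bad, parts), "cyl")
})

test_that("surface areas use lateral closed forms and fur exceeds skin", {
  free <- fixture_cylinder(length = 1, skin_radius = 0.3, fur_depth = 0.04)
  expect_equal(free$skin_area_lateral, 2 * pi * 0.3 * 1)
  g <- fixture_geometry("winter")
  expect_true(all(g$fur_area > g$skin_area))
  # leg and neck rows carry no end areas
  legs <- g[g$part %in% c("front_leg", "hind_leg", "neck"), ]
  expect_equal(legs$skin_area, legs$skin_area_lateral)
})

test_that("whole-bear areas track the live-bear allometric equations", {
  va <- validate_allometry()
  gl <- glance(va)
  expect_lt(gl$max_abs_fur_dev_pct, 6)
  expect_lt(gl$max_abs_skin_dev_pct, 7)
  # spot check at the average male: 0.11 * 409^0.67 ~ 6.18 m^2, within 6%
  v <- va[abs(va$length - 2.3) < 1e-9, ]
  expect_lt(abs(v$fur_area - 0.11 * v$mass^0.67) / (0.11 * v$mass^0.67), 0.06)
})

test_that("infeasible fur depth fails loudly", {
  specs <- part_specs()
  specs$fur_depth <- rep(0.5, 5)   # deeper than any scaled radius
  expect_error(build_geometry(init_composition(2.0, 2.25, "female"), specs),
               "fur depth")
})
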