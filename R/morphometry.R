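# Body composition and photo-scaled body-part geometry.
#
# Total mass is split into structural mass (skeletal, set by straight-line
# body length, non-catabolizable) and storage mass (fat + lean storage).
# Geometry: parts are cylinders (neck, torso, legs) and a truncated cone
# (head) whose photo proportions are scaled by straight-line length; fur
# depth is subtracted for skin dimensions, mass is apportioned by part
# volume, radii are adjusted uniformly to bring flesh+fat density to
# ~1000 kg/m^3, and 75% of body fat is laid down as a subcutaneous annulus
# on every part except the head.

#' Initial body-composition anchor table
#'
#' The published initial compositions for the 18 simulated bears: six
#' straight-line lengths (three per sex), each in poor / average / excellent
#' condition (total mass 1.5 / 2.25 / 3 x structural mass). Masses in kg,
#' energy in MJ.
#'
#' @return A tibble with one row per (length, condition).
#' @export
composition_anchors <- function() {
  base <- tibble(
    sex = rep(c("female", "male"), each = 3),
    length = c(1.85, 2.00, 2.10, 2.15, 2.30, 2.45),
    structural = c(95, 120, 138, 148, 182, 220),
    total_pr = c(142, 179, 208, 223, 273, 330),
    total_av = c(213, 269, 311, 334, 409, 494),
    total_ex = c(283, 359, 415, 445, 545, 659),
    fat_pr = c(30, 37, 43, 33, 40, 48),
    fat_av = c(74, 94, 108, 82, 100, 121),
    fat_ex = c(119, 150, 174, 130, 160, 193),
    lean_pr = c(17, 22, 26, 42, 51, 62),
    lean_av = c(44, 56, 64, 104, 127, 154),
    lean_ex = c(71, 89, 103, 167, 204, 246),
    energy_pr = c(1236, 1562, 1808, 1448, 1772, 2142),
    energy_av = c(3091, 3905, 4521, 3619, 4430, 5355),
    energy_ex = c(4945, 6248, 7233, 5791, 7089, 8569))
  tidyr::pivot_longer(base, -c("sex", "length", "structural"),
                      names_to = c(".value", "condition"), names_sep = "_") |>
    dplyr::mutate(condition = dplyr::recode(.data$condition, pr = "poor",
                                            av = "average", ex = "excellent"))
}

#' Structural mass from straight-line body length
#'
#' Monotone (Hyman) spline through the six published (length, structural
#' mass) anchors; outside the anchor range a power law fitted to the same
#' anchors is used, so the curve extends smoothly to the 1.8-2.5 m
#' validation sweep. A user-supplied function of length may replace it.
#'
#' @param length straight-line body length, m (vectorised).
#' @param fn optional replacement function `length -> kg`.
#' @return Structural mass, kg.
#' @export
structural_mass <- function(length, fn = NULL) {
  if (!is.null(fn)) return(fn(length))
  anchors <- composition_anchors() |>
    dplyr::distinct(.data$length, .data$structural)
  sp <- splinefun(anchors$length, anchors$structural, method = "hyman")
  pw <- coef(lm(log(structural) ~ log(length), data = anchors))
  inside <- length >= min(anchors$length) & length <= max(anchors$length)
  out <- numeric(length(length))
  out[inside] <- sp(length[inside])
  out[!inside] <- exp(pw[1]) * length[!inside]^pw[2]
  out
}

# fraction of storage mass that is fat, per sex, fitted once to the
# 18 anchor rows (near-constant within sex: ~0.627 female, ~0.440 male)
storage_fat_fraction <- function(sex) {
  anchors <- composition_anchors() |>
    dplyr::mutate(frac = .data$fat / (.data$total - .data$structural)) |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(frac = mean(.data$frac))
  anchors$frac[match(sex, anchors$sex)]
}

#' Energy stores from body composition
#'
#' `E = 39.3 F + 18.0 * 0.22 * L` MJ: fat at 39.3 MJ/kg plus the protein in
#' lean storage mass (22% protein at 18.0 MJ/kg).
#'
#' @param fat_mass,lean_mass catabolizable fat and lean storage mass, kg.
#' @return Energy stores, MJ.
#' @export
energy_stores <- function(fat_mass, lean_mass) {
  .const$e_fat * fat_mass + .const$e_lean * lean_mass
}

#' Initialise a bear's body composition
#'
#' @param straight_length straight-line body length, m.
#' @param condition_multiplier total mass as a multiple of structural mass
#'   (>= 1; poor 1.5, average 2.25, excellent 3.0).
#' @param sex `"female"` or `"male"` (sets the fat/lean split of storage).
#' @param structural_fn optional replacement for [structural_mass()].
#' @param fat_split optional explicit fat fraction of storage mass.
#' @return One-row tibble with `straight_length`, `sex`, `condition_multiplier`,
#'   `structural_mass`, `fat_mass`, `lean_mass`, `total_mass`, `energy_mj`.
#' @export
#' @examples
#' init_composition(2.00, 2.25, "female")
init_composition <- function(straight_length, condition_multiplier, sex,
                             structural_fn = NULL, fat_split = NULL) {
  stopifnot(condition_multiplier >= 1)
  sex <- match.arg(sex, c("female", "male"))
  s <- structural_mass(straight_length, structural_fn)
  m <- condition_multiplier * s
  storage <- m - s
  split <- fat_split %||% storage_fat_fraction(sex)
  f <- split * storage
  l <- storage - f
  tibble(straight_length = straight_length, sex = sex,
         condition_multiplier = condition_multiplier,
         structural_mass = s, fat_mass = f, lean_mass = l,
         total_mass = m, energy_mj = energy_stores(f, l))
}

#' The 18-bear study population
#'
#' Six straight-line lengths (2.15/2.30/2.45 m males, 1.85/2.00/2.10 m
#' females), each in poor, average and excellent condition.
#'
#' @inheritParams init_composition
#' @return An 18-row composition tibble with a `condition` label column.
#' @export
generate_population <- function(structural_fn = NULL) {
  grid <- tidyr::expand_grid(
    len_sex = list(c(1.85, "female"), c(2.00, "female"), c(2.10, "female"),
                   c(2.15, "male"), c(2.30, "male"), c(2.45, "male")),
    condition = c("poor", "average", "excellent"))
  mult <- c(poor = 1.5, average = 2.25, excellent = 3.0)
  purrr::pmap_dfr(grid, function(len_sex, condition) {
    init_composition(as.numeric(len_sex[1]), mult[[condition]], len_sex[2],
                     structural_fn) |>
      dplyr::mutate(condition = condition, .after = "sex")
  })
}

#' Photo-to-animal scaling factor
#'
#' `straight-line length / (head + neck + torso photo lengths)`, in cm of
#' animal per photo unit: a bear of 2.30 m with photo lengths summing to
#' 11.5 units scales by 20.
#'
#' @param specs part-spec tibble (see [part_specs()]).
#' @param straight_length straight-line body length, m.
#' @return Scalar multiplier (cm per photo unit).
#' @export
scaling_factor <- function(specs, straight_length) {
  core <- specs$photo_length[specs$part %in% c("head", "neck", "torso")]
  if (any(core <= 0) || straight_length <= 0)
    abort("lengths must be positive")
  straight_length * 100 / sum(core)
}

#' Build body-part geometry for a composition
#'
#' Scales the photo proportions to the bear's length, subtracts twice the
#' fur depth for skin diameters, apportions total and fat mass by part
#' volume, adjusts all radii by a single multiplicative factor until the
#' whole-body flesh+fat density is within 1% of 1000 kg/m^3, and solves
#' each part's subcutaneous fat annulus thickness. Bears of the same length
#' in different conditions share part lengths and differ only in diameters.
#'
#' @param composition one-row tibble from [init_composition()].
#' @param specs part-spec tibble from [part_specs()] (its `fur_depth`
#'   column selects the seasonal coat).
#' @return A tibble with one row per part: dimensions (m), layer radii,
#'   fat thickness, areas (m^2, see [surface_areas()]) and allocated
#'   masses (kg). Leg rows carry `count = 2`.
#' @export
build_geometry <- function(composition, specs = part_specs()) {
  m_total <- composition$total_mass
  f_total <- composition$fat_mass
  k <- scaling_factor(specs, composition$straight_length)
  g <- specs |>
    dplyr::mutate(
      length = .data$photo_length * k / 100,
      outer_radius = .data$photo_diam * k / 200,
      skin_radius = .data$outer_radius - .data$fur_depth)
  if (any(g$skin_radius <= 0))
    abort(sprintf("fur depth exceeds scaled radius for part(s): %s",
                  paste(g$part[g$skin_radius <= 0], collapse = ", ")))
  part_volume <- function(g, r) {
    ifelse(g$shape == "truncated_cone",
           pi * g$length / 3 * ((g$taper * r)^2 + g$taper * r^2 + r^2) * g$count,
           pi * r^2 * g$length * g$count)
  }
  v0 <- part_volume(g, g$skin_radius)
  target_v <- m_total / .const$rho_body
  # volumes are quadratic in radius at fixed length, so one multiplicative
  # step lands exactly on the target density; the loop guards round-off
  for (i in 1:5) {
    adj <- sqrt(target_v / sum(part_volume(g, g$skin_radius)))
    g$skin_radius <- g$skin_radius * adj
    if (abs(sum(part_volume(g, g$skin_radius)) - target_v) / target_v < 1e-10) break
  }
  g$volume <- part_volume(g, g$skin_radius)
  dens <- m_total / sum(g$volume)
  if (abs(dens - .const$rho_body) / .const$rho_body > 0.01)
    abort("density adjustment failed to reach 1000 kg/m^3 within 1%")
  g$mass <- m_total * g$volume / sum(g$volume)
  g <- allocate_fat(composition, g)
  g$fur_radius <- g$skin_radius + g$fur_depth
  g <- surface_areas(g)
  attr(g, "part_list") <- lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
  g
}

#' Allocate subcutaneous fat to body parts
#'
#' 75% of total body fat is subcutaneous (density 901 kg/m^3) and is
#' distributed over all parts except the head in proportion to part volume;
#' each part's annulus thickness is solved in closed form from the annulus
#' volume. The head never carries subcutaneous fat.
#'
#' @param composition one-row composition tibble.
#' @param parts geometry tibble with `skin_radius`, `length`, `volume`,
#'   `count`, `shape` columns.
#' @return `parts` with `fat_mass`, `fat_thickness`, `flesh_radius` filled.
#' @export
allocate_fat <- function(composition, parts) {
  v_sc <- .const$fat_subcut * composition$fat_mass / .const$rho_fat
  eligible <- parts$part != "head"
  share <- ifelse(eligible, parts$volume / sum(parts$volume[eligible]), 0)
  v_part <- v_sc * share                      # m^3, all copies of the part
  parts$fat_mass <- .const$fat_subcut * composition$fat_mass * share
  r <- parts$skin_radius
  # annulus volume per copy: v = pi L (r^2 - r_flesh^2)
  arg <- r^2 - v_part / (parts$count * pi * parts$length)
  if (any(arg < 0))
    abort(sprintf("fat volume exceeds part volume for part(s): %s",
                  paste(parts$part[arg < 0], collapse = ", ")))
  parts$flesh_radius <- ifelse(eligible, sqrt(arg), r)
  parts$fat_thickness <- r - parts$flesh_radius
  parts
}

#' Skin and fur surface areas
#'
#' Lateral areas plus the end areas that exchange with the environment:
#' the torso keeps its two end disks minus the joined neck and four leg end
#' areas; the neck and legs are lateral-only (joined ends and ground
#' contact); the head keeps its muzzle end but not its joined base.
#' Fur areas use the skin radius plus fur depth.
#'
#' @param parts geometry tibble with `skin_radius`, `fur_radius` (or
#'   `fur_depth`), `length`, `count`, `shape`, `taper` columns.
#' @return `parts` with `skin_area`, `fur_area`, `skin_area_lateral`,
#'   `fur_area_lateral` columns (m^2, totals over part copies).
#' @export
surface_areas <- function(parts) {
  if (is.null(parts$fur_radius)) parts$fur_radius <- parts$skin_radius + parts$fur_depth
  area_at <- function(r) {
    lat <- ifelse(parts$shape == "truncated_cone",
      pi * (parts$taper * r + r) *
        sqrt(parts$length^2 + (r - parts$taper * r)^2),
      2 * pi * r * parts$length) * parts$count
    i_t <- which(parts$part == "torso")
    i_n <- which(parts$part == "neck")
    i_h <- which(parts$part == "head")
    legs <- parts$part %in% c("front_leg", "hind_leg")
    ends <- numeric(nrow(parts))
    ends[i_t] <- 2 * pi * r[i_t]^2 - pi * r[i_n]^2 -
      sum(parts$count[legs] * pi * r[legs]^2)
    ends[i_h] <- pi * (parts$taper[i_h] * r[i_h])^2
    list(lateral = lat, total = lat + ends)
  }
  skin <- area_at(parts$skin_radius)
  fur <- area_at(parts$fur_radius)
  parts$skin_area_lateral <- skin$lateral
  parts$skin_area <- skin$total
  parts$fur_area_lateral <- fur$lateral
  parts$fur_area <- fur$total
  parts
}

#' Check whole-bear areas against live-bear allometric equations
#'
#' Builds geometry for average-condition bears (total mass 2.25 x
#' structural) across a range of straight-line lengths and compares
#' whole-bear skin and fur surface areas to the live-bear predictive
#' equations `0.09 * mass^0.67` and `0.11 * mass^0.67` (m^2, mass in kg).
#'
#' @param lengths straight-line lengths to sweep, m.
#' @param condition_multiplier condition class (default average, 2.25).
#' @param specs part-spec table; defaults to the reference-coat proportions.
#' @return A tibble of class `bear_allometry` with per-length areas,
#'   expectations, and percent deviations; `glance()` reports the maximum
#'   absolute deviations.
#' @export
#' @examples
#' glance(validate_allometry())
validate_allometry <- function(lengths = seq(1.8, 2.5, by = 0.1),
                               condition_multiplier = 2.25,
                               specs = part_specs("reference")) {
  rows <- purrr::map_dfr(lengths, function(len) {
    sex <- if (len <= 2.10) "female" else "male"
    comp <- init_composition(len, condition_multiplier, sex)
    geo <- build_geometry(comp, specs)
    tibble(length = len, mass = comp$total_mass,
           skin_area = sum(geo$skin_area), fur_area = sum(geo$fur_area))
  })
  out <- rows |>
    dplyr::mutate(
      skin_expected = 0.09 * .data$mass^0.67,
      fur_expected = 0.11 * .data$mass^0.67,
      skin_dev_pct = 100 * (.data$skin_area / .data$skin_expected - 1),
      fur_dev_pct = 100 * (.data$fur_area / .data$fur_expected - 1))
  class(out) <- c("bear_allometry", class(out))
  out
}

#' @rdname validate_allometry
#' @param x a `bear_allometry` tibble.
#' @param ... unused.
#' @method glance bear_allometry
#' @export
glance.bear_allometry <- function(x, ...) {
  tibble(n_lengths = nrow(x),
         max_abs_skin_dev_pct = max(abs(x$skin_dev_pct)),
         max_abs_fur_dev_pct = max(abs(x$fur_dev_pct)),
         skin_in_bounds = max(abs(x$skin_dev_pct)) < 7,
         fur_in_bounds = max(abs(x$fur_dev_pct)) < 6)
}
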