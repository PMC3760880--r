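# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a fasting simulation
#'
#' @param x a `bear_fast` object from [run_fast()].
#' @param ... unused.
#' @return The per-interval tibble (date, composition, demand, flags).
#' @method tidy bear_fast
#' @export
tidy.bear_fast <- function(x, ...) x$intervals

#' @rdname tidy.bear_fast
#' @method glance bear_fast
#' @export
glance.bear_fast <- function(x, ...) {
  tibble(survived = x$survived, survival_day = x$survival_day,
         pct_energy_remaining = x$pct_energy_remaining,
         avg_daily_weight_loss_kg = x$avg_daily_weight_loss,
         panting_hour_pct = 100 * x$panting_hour_fraction,
         unresolvable_hour_pct = 100 * x$unresolvable_hour_fraction,
         elevated_demand_days = x$elevated_demand_days)
}

#' @rdname tidy.bear_fast
#' @param object a `bear_fast` object.
#' @method autoplot bear_fast
#' @export
autoplot.bear_fast <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::select("date", "total_mass", "fat_mass", "lean_mass") |>
    tidyr::pivot_longer(-"date", names_to = "pool", values_to = "kg")
  ggplot2::ggplot(d, ggplot2::aes(.data$date, .data$kg, colour = .data$pool)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "mass (kg)",
                  title = sprintf("%.2f m %s, %.2fx structural: %s",
                                  object$bear$straight_length,
                                  object$bear$sex,
                                  object$bear$condition_multiplier,
                                  if (object$survived) "survived"
                                  else sprintf("starved day %d", object$survival_day)))
}

#' @export
print.bear_fast <- function(x, ...) {
  cat(sprintf("<bear_fast> %.2f m %s, %.1f kg start; %s\n",
              x$bear$straight_length, x$bear$sex, x$bear$total_mass,
              if (x$survived)
                sprintf("survived %d days with %.1f%% energy remaining",
                        x$scenario$duration_days, x$pct_energy_remaining)
              else sprintf("starved on day %d", x$survival_day)))
  cat(sprintf("  avg daily weight loss %.2f kg/d; panting %.1f%% of hours\n",
              x$avg_daily_weight_loss, 100 * x$panting_hour_fraction))
  invisible(x)
}

#' Tidy a minimum-energy-density estimate
#'
#' @param x a `bear_med` object from [minimum_energy_density()].
#' @param ... unused.
#' @return The size-sweep tibble.
#' @method tidy bear_med
#' @export
tidy.bear_med <- function(x, ...) x$sweep

#' @rdname tidy.bear_med
#' @method glance bear_med
#' @export
glance.bear_med <- function(x, ...) {
  tibble(min_energy_density_mj_kg = x$min_density, flag = x$flag,
         n_sweep = nrow(x$sweep), length = x$length, sex = x$sex)
}

#' @rdname tidy.bear_med
#' @param object a `bear_med` object.
#' @method autoplot bear_med
#' @export
autoplot.bear_med <- function(object, ...) {
  p <- ggplot2::ggplot(object$sweep,
                       ggplot2::aes(.data$energy_density, .data$fraction_survived)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "initial energy density (MJ/kg lean mass)",
                  y = "fraction of fast survived")
  if (!is.null(object$fit))
    p <- p + ggplot2::geom_abline(intercept = coef(object$fit)[1],
                                  slope = coef(object$fit)[2],
                                  linetype = 2)
  if (!is.na(object$min_density))
    p <- p + ggplot2::geom_vline(xintercept = object$min_density, colour = "red")
  p
}

#' @rdname validate_allometry
#' @param object a `bear_allometry` tibble.
#' @method autoplot bear_allometry
#' @export
autoplot.bear_allometry <- function(object, ...) {
  d <- object |>
    dplyr::select("mass", "skin_area", "fur_area",
                  "skin_expected", "fur_expected") |>
    tidyr::pivot_longer(-"mass", names_to = c("layer", "kind"),
                        names_sep = "_", values_to = "area")
  ggplot2::ggplot(d, ggplot2::aes(.data$mass, .data$area,
                                  colour = .data$layer,
                                  linetype = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "total mass (kg)", y = expression(area ~ (m^2)))
}

#' @rdname chamber_sweep
#' @param object a `bear_chamber` tibble.
#' @param ... unused.
#' @method autoplot bear_chamber
#' @export
autoplot.bear_chamber <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_chamber, .data$q_gen)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "chamber temperature (°C)",
                  y = "steady-state metabolic rate (W)")
}
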