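# One-dimensional substrate heat-conduction column.
#
# A 10-node column, geometrically spaced to 2 m, is advanced hourly with a
# backward-Euler finite-volume scheme (unconditionally stable). The surface
# node is forced by the hourly surface energy balance -- absorbed solar,
# longwave exchange with the effective sky temperature, and convective
# exchange with the air -- or, alternatively, by a prescribed surface
# temperature (used for verification against an independent diffusion
# solution). The scheme is conservative: per step, the change in stored
# heat equals the boundary flux times the step.

#' Substrate thermal properties
#'
#' @param substrate `"soil"` or `"snow"`.
#' @return list with conductivity `k` (W/m.degC), volumetric heat capacity
#'   `rho_c` (J/m^3.degC) and shortwave `albedo`.
#' @export
ground_props <- function(substrate = c("soil", "snow")) {
  switch(match.arg(substrate),
    soil = list(k = 1.0, rho_c = 2.0e6, albedo = 0.25),
    snow = list(k = 0.2, rho_c = 0.4e6, albedo = 0.80))
}

# geometric node depths: z[1] = 0 (surface), z[n] = depth
ground_nodes <- function(n_nodes = 10, depth = 2, ratio = 1.6) {
  inc <- ratio^(0:(n_nodes - 2))
  z <- c(0, cumsum(inc / sum(inc) * depth))
  z[seq_len(n_nodes)]
}

#' Advance a substrate heat-conduction column
#'
#' @param forcing tibble with one row per time step: `t_air`, `wind`,
#'   `solar_flux`, `t_sky` (energy-balance mode) or `t_surface`
#'   (prescribed mode).
#' @param props property list from [ground_props()]; may instead be a list
#'   of such lists, one per step, to switch substrate mid-series.
#' @param dt step length, s.
#' @param n_nodes,depth,ratio column discretisation.
#' @param surface boundary mode.
#' @param t_init initial column temperature, degC (scalar or per-node).
#' @param cap_at_zero cap the surface temperature at 0 degC (snow surface
#'   cannot exceed melt temperature).
#' @param max_iter,tol Newton iteration controls for the nonlinear surface
#'   balance; non-convergence is an error, never silent.
#' @return list of class `ground_column`: `temps` (steps x nodes matrix),
#'   `z` (node depths), `flux_in` (boundary flux each step, W/m^2),
#'   `stored` (column heat content each step, J/m^2 relative to 0 degC).
#' @export
ground_column <- function(forcing, props = ground_props("soil"), dt = 3600,
                          n_nodes = 10, depth = 2, ratio = 1.6,
                          surface = c("energy_balance", "prescribed"),
                          t_init = NULL, cap_at_zero = FALSE,
                          max_iter = 50, tol = 1e-6, substeps = 6) {
  surface <- match.arg(surface)
  z <- ground_nodes(n_nodes, depth, ratio)
  n <- n_nodes
  per_step <- !is.null(props$k)
  get_props <- function(i) if (per_step) props else props[[i]]
  steps <- nrow(forcing)
  t0 <- t_init %||% if (surface == "prescribed") forcing$t_surface[1] else forcing$t_air[1]
  temp <- rep_len(t0, n)
  temps <- matrix(NA_real_, steps, n)
  flux_in <- numeric(steps)
  stored <- numeric(steps)

  for (s in seq_len(steps)) {
    pr <- get_props(s)
    dz <- diff(z)
    cap <- pr$rho_c * c(dz[1] / 2, (z[-c(1, 2)] - z[-c(n - 1, n)]) / 2, dz[n - 1] / 2)
    g <- pr$k / dz                      # inter-node conductances, W/m^2.degC
    f <- forcing[s, ]
    if (surface == "prescribed") {
      # Dirichlet surface: solve interior nodes implicitly, sub-stepping
      # with the surface value interpolated linearly across the step
      dts <- dt / substeps
      a_mat <- matrix(0, n - 1, n - 1)
      for (i in 2:n) {
        j <- i - 1
        a_mat[j, j] <- cap[i] / dts + g[i - 1] + if (i < n) g[i] else 0
        if (j > 1) a_mat[j, j - 1] <- -g[i - 1]
        if (i < n) a_mat[j, j + 1] <- -g[i]
      }
      ts_prev <- if (s == 1) temp[1] else forcing$t_surface[s - 1]
      flux_acc <- 0
      for (ss in seq_len(substeps)) {
        ts_now <- ts_prev + (f$t_surface - ts_prev) * ss / substeps
        b <- cap[-1] / dts * temp[-1]
        b[1] <- b[1] + g[1] * ts_now
        temp <- c(ts_now, solve(a_mat, b))
        flux_acc <- flux_acc + g[1] * (ts_now - temp[2])
      }
      flux_in[s] <- flux_acc / substeps
    } else {
      h <- 5.7 + 3.8 * f$wind           # surface convective coefficient
      eps <- 0.95
      l_down <- .const$sigma * (f$t_sky + .const$t0)^4
      dts <- dt / substeps
      base <- matrix(0, n, n)
      for (i in seq_len(n)) {
        base[i, i] <- cap[i] / dts +
          (if (i > 1) g[i - 1] else 0) + (if (i < n) g[i] else 0)
        if (i > 1) base[i, i - 1] <- -g[i - 1]
        if (i < n) base[i, i + 1] <- -g[i]
      }
      flux_acc <- 0
      for (ss in seq_len(substeps)) {
        t_old <- temp
        t_new <- temp
        converged <- FALSE
        for (it in seq_len(max_iter)) {
          t1k <- t_new[1] + .const$t0
          q  <- (1 - pr$albedo) * f$solar_flux +
            eps * (l_down - .const$sigma * t1k^4) + h * (f$t_air - t_new[1])
          dq <- -4 * eps * .const$sigma * t1k^3 - h
          a_mat <- base
          b <- cap / dts * t_old
          # linearised surface flux: q + dq * (T1_new - T1_iter)
          a_mat[1, 1] <- a_mat[1, 1] - dq
          b[1] <- b[1] + q - dq * t_new[1]
          t_next <- solve(a_mat, b)
          if (max(abs(t_next - t_new)) < tol) {
            t_new <- t_next
            converged <- TRUE
            break
          }
          t_new <- t_next
        }
        if (!converged)
          abort(sprintf("ground column surface balance failed to converge at step %d", s))
        temp <- t_new
        t1k <- temp[1] + .const$t0
        flux_acc <- flux_acc + (1 - pr$albedo) * f$solar_flux +
          eps * (l_down - .const$sigma * t1k^4) + h * (f$t_air - temp[1])
      }
      flux_in[s] <- flux_acc / substeps
      if (cap_at_zero && temp[1] > 0) temp[1] <- 0
    }
    temps[s, ] <- temp
    dz_all <- diff(z)
    cap_now <- get_props(s)$rho_c *
      c(dz_all[1] / 2, (z[-c(1, 2)] - z[-c(n - 1, n)]) / 2, dz_all[n - 1] / 2)
    stored[s] <- sum(cap_now * temp)
  }
  structure(list(temps = temps, z = z, flux_in = flux_in, stored = stored),
            class = "ground_column")
}

#' Hourly substrate surface temperature for a microenvironment table
#'
#' Runs the substrate column over the full hourly series (with a two-day
#' spin-up replay of the first day) and returns the surface-node
#' temperature. Hours flagged as snow use snow properties and are capped at
#' 0 degC.
#'
#' @param env hourly tibble with `t_air`, `wind`, `solar_flux`, `t_sky`,
#'   `snow`.
#' @param props optional single property list overriding the per-hour
#'   soil/snow switch.
#' @return Numeric vector of surface temperatures, degC.
#' @export
ground_temperature <- function(env, props = NULL) {
  if (nrow(env) < 48) {
    # short series: replicate to give the column context, then trim
    reps <- ceiling(48 / nrow(env)) + 1
    idx <- rep(seq_len(nrow(env)), reps)
    full <- env[idx, ]
    keep <- seq(nrow(full) - nrow(env) + 1, nrow(full))
  } else {
    spin <- env[seq_len(48), ]
    full <- dplyr::bind_rows(spin, env)
    keep <- seq(49, nrow(full))
  }
  plist <- if (!is.null(props)) props else
    purrr::map(full$snow, ~ ground_props(if (isTRUE(.x)) "snow" else "soil"))
  col <- ground_column(full, props = plist, surface = "energy_balance")
  ts <- col$temps[, 1]
  snowy <- if (!is.null(props)) rep(FALSE, nrow(full)) else full$snow
  ts[snowy & ts > 0] <- 0
  ts[keep]
}
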