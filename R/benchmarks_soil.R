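#' Infiltration benchmark (switching top flux, free drainage)
#'
#' Runs the 1D vertical infiltration scenario: a 200 cm column at a uniform
#' initial head of -400 cm, a prescribed influx of 100 cm/d at the surface
#' switching to a ponded head of 0 cm once the surface saturates, and free
#' drainage (unit total-head gradient) at the bottom.  Water-content
#' profiles are recorded at the scenario's conventional output times (sand
#' 0.1/0.2/0.3 d, loam 0.2/0.5/1 d, clay 0.1/0.2/0.5 d) unless overridden.
#'
#' @param soil_name one of \code{"sand"}, \code{"loam"}, \code{"clay"}
#' @param dz cell size (cm)
#' @param out_times output times (d); defaults per soil
#' @param dt_max time-step cap (d)
#' @param J influx (cm/d)
#' @param psi_i initial head (cm)
#' @param depth column depth (cm)
#' @param face_k inter-cell conductivity scheme (see
#'   \code{\link{richards_step}})
#' @return a list of class \code{m21_result}: \code{z} (depth grid, cm,
#'   positive downward), \code{theta} (matrix, one column per output time),
#'   \code{times}, \code{cum_infiltration} at each output time (cm),
#'   \code{soil}, \code{max_mass_err}
#' @export
run_infiltration_benchmark <- function(soil_name, dz = 0.1, out_times = NULL,
                                       dt_max = NULL, J = 100,
                                       psi_i = -400, depth = 200,
                                       face_k = NULL) {
  soil <- if (inherits(soil_name, "vg_soil")) soil_name
          else soil_catalogue(soil_name)
  if (is.null(out_times))
    out_times <- switch(soil$name,
                        sand = c(0.1, 0.2, 0.3),
                        loam = c(0.2, 0.5, 1),
                        clay = c(0.1, 0.2, 0.5),
                        stop("no default output times for soil '",
                             soil$name, "'"))
  if (is.null(face_k)) face_k <- "arithmetic"
  if (is.null(dt_max)) {
    # cap the step so the wetting front advances at most ~1.5 cm per step
    # (temporal smearing otherwise dominates for the fast sand front)
    theta_i <- water_content(psi_i, soil)
    theta_sur <- if (soil$K_sat > J)
      stats::uniroot(function(th) hydraulic_conductivity(th, soil) - J,
                     c(theta_i, soil$theta_sat), tol = 1e-12)$root
    else soil$theta_sat
    v <- (hydraulic_conductivity(theta_sur, soil) -
            hydraulic_conductivity(theta_i, soil)) / (theta_sur - theta_i)
    dt_max <- min(0.01, 1.5 / max(v, 1))
  }
  g <- soil_grid_vertical(depth, round(depth / dz))
  st <- soil_state(g, soil, psi_i)
  bcs <- list(top = bc_switch_influx(J, 0), bottom = bc_free_drainage())
  cum_at <- numeric(length(out_times))
  theta <- matrix(NA_real_, nrow = g$n, ncol = length(out_times))
  run <- richards_run(st, g, soil, bcs, max(out_times),
                      out_times = out_times, dt_max = dt_max,
                      face_k = face_k)
  for (k in seq_along(out_times)) theta[, k] <- run$states[[k]]$theta
  fs <- run$flux_series
  cumJ <- cumsum(fs$top * fs$dt)
  for (k in seq_along(out_times))
    cum_at[k] <- cumJ[which.min(abs(fs$t - out_times[k]))]
  structure(list(z = -g$z, theta = theta, times = out_times,
                 cum_infiltration = cum_at / g$area, soil = soil,
                 psi_i = psi_i, J = J,
                 max_mass_err = run$max_mass_err),
            class = "m21_result")
}

#' Analytic reference for the infiltration benchmark
#'
#' Builds the traveling-wave profiles matching
#' \code{\link{run_infiltration_benchmark}}.  For soils whose saturated
#' conductivity exceeds the influx the surface never ponds: the surface
#' content solves \eqn{K(\theta_{sur}) = J} and the cumulative infiltration
#' is exactly \eqn{J\,t}.  For ponding soils the surface content is
#' \eqn{\theta_{sat}} and the wave is anchored with the supplied cumulative
#' infiltration when available.
#'
#' @param soil a \code{vg_soil} or soil name
#' @param t time (d)
#' @param J influx (cm/d)
#' @param psi_i initial head (cm)
#' @param cum_infiltration cumulative infiltration (cm) for anchoring a
#'   ponded-scenario wave (ignored for non-ponding soils)
#' @return a \code{traveling_wave} (see \code{\link{infiltration_profile}})
#' @export
infiltration_reference <- function(soil, t, J = 100, psi_i = -400,
                                   cum_infiltration = NULL) {
  if (is.character(soil)) soil <- soil_catalogue(soil)
  theta_i <- water_content(psi_i, soil)
  if (soil$K_sat > J) {
    theta_sur <- stats::uniroot(
      function(th) hydraulic_conductivity(th, soil) - J,
      c(theta_i, soil$theta_sat), tol = 1e-14)$root
    infiltration_profile(soil, theta_i, theta_sur, t,
                         cum_infiltration = J * t)
  } else {
    infiltration_profile(soil, theta_i, soil$theta_sat, t,
                         cum_infiltration = cum_infiltration)
  }
}

#' Evaporation benchmark (switching top efflux)
#'
#' Runs the 1D drying scenario: a 100 cm column, uniform initial head
#' (-40 cm for sand, -200 cm otherwise), a prescribed surface efflux that
#' switches to a Dirichlet head of -10000 cm once the surface dries to that
#' head, and a no-flux bottom.  Simulation time 10 d.
#'
#' @param scenario 1 (sand, 0.1 cm/d), 2 (loam, 0.1), 3 (loam, 0.3) or
#'   4 (clay, 0.3); alternatively a soil name with \code{J_pot} given
#' @param dz cell size (cm)
#' @param t_end simulated time (d)
#' @param dt_max step cap (d)
#' @param J_pot potential evaporation (cm/d), filled from the scenario id
#' @return a list of class \code{m22_result}: \code{t}, \code{flux}
#'   (actual evaporation, cm/d, positive out of the soil), scenario
#'   metadata, \code{max_mass_err}
#' @export
run_evaporation_benchmark <- function(scenario, dz = 1, t_end = 10,
                                      dt_max = 0.01, J_pot = NULL) {
  scn <- list(`1` = list(soil = "sand", J = 0.1, psi_i = -40),
              `2` = list(soil = "loam", J = 0.1, psi_i = -200),
              `3` = list(soil = "loam", J = 0.3, psi_i = -200),
              `4` = list(soil = "clay", J = 0.3, psi_i = -200))
  if (is.numeric(scenario) && scenario %in% 1:4) {
    s <- scn[[as.character(scenario)]]
  } else {
    s <- list(soil = scenario, J = J_pot, psi_i = -200)
    if (is.null(J_pot)) stop("J_pot required for a custom scenario")
  }
  soil <- soil_catalogue(s$soil)
  # drying fronts are mm-scale at the surface: graded grid, dz at depth
  g <- soil_grid_vertical_graded(100, dz_top = 0.01, dz_max = dz)
  st <- soil_state(g, soil, s$psi_i)
  bcs <- list(top = bc_switch_efflux(s$J, -10000), bottom = bc_no_flux())
  run <- richards_run(st, g, soil, bcs, t_end, out_times = t_end,
                      dt_max = dt_max)
  fs <- run$flux_series
  structure(list(t = fs$t, flux = -fs$top / g$area, soil = soil,
                 J_pot = s$J, psi_i = s$psi_i,
                 max_mass_err = run$max_mass_err),
            class = "m22_result")
}

#' Analytic reference for the evaporation benchmark
#'
#' @param scenario scenario id as in \code{\link{run_evaporation_benchmark}}
#' @return a \code{desorptivity} object with \code{t_pot}/\code{t_prime}
#'   filled; evaluate with \code{\link{evaporation_rate}}
#' @export
evaporation_reference <- function(scenario) {
  scn <- list(`1` = list(soil = "sand", J = 0.1, psi_i = -40),
              `2` = list(soil = "loam", J = 0.1, psi_i = -200),
              `3` = list(soil = "loam", J = 0.3, psi_i = -200),
              `4` = list(soil = "clay", J = 0.3, psi_i = -200))
  s <- scn[[as.character(scenario)]]
  soil <- soil_catalogue(s$soil)
  desorptivity(soil, theta_i = water_content(s$psi_i, soil),
               theta_sur = water_content(-10000, soil), J_pot = s$J)
}

#' Radially symmetric single-root uptake benchmark
#'
#' Runs the 1D radially symmetric drying problem around a single root:
#' uniform initial head, a prescribed uptake flux at the root surface
#' switching to a Dirichlet head at the limiting value, no flux at the
#' outer radius, gravity off.  Reports the onset of stress (first switch to
#' the Dirichlet mode) and the radial profile at that moment.
#'
#' @param scn a \code{\link{radial_scenario}}
#' @param n_cells radial cells (geometrically graded toward the root)
#' @param first_cell innermost cell width (cm)
#' @param dt_max step cap (d)
#' @param t_max simulation cap (d)
#' @return a list of class \code{c11_result}: \code{t_onset} (d), \code{r}
#'   (cell centres, cm), \code{psi_onset}, \code{theta_onset}, plus the
#'   full time series of the root-surface flux
#' @export
run_radial_uptake_benchmark <- function(scn, n_cells = 120,
                                        first_cell = 1e-3,
                                        dt_max = 0.01, t_max = 30) {
  stopifnot(inherits(scn, "radial_scenario"))
  g <- soil_grid_radial(scn$r_root, scn$r_out, n = n_cells,
                        first_cell = first_cell)
  st <- soil_state(g, scn$soil, scn$psi_i)
  bcs <- list(inner = bc_switch_efflux(scn$q_root, scn$psi_lim),
              outer = if (scn$q_out == 0) bc_no_flux()
                      else bc_flux(scn$q_out))
  onset <- NA_real_
  psi_onset <- NULL
  st_cur <- st; bc_state <- NULL; dt <- 1e-4
  times <- numeric(0); fluxes <- numeric(0)
  while (st_cur$t < t_max) {
    res <- richards_step(st_cur, g, scn$soil, bcs, min(dt, t_max - st_cur$t),
                         bc_state = bc_state)
    if (!res$converged) {
      dt <- dt / 2
      if (dt < 1e-10) stop("radial solver stalled at t = ", st_cur$t)
      next
    }
    dt_used <- min(dt, t_max - st_cur$t)
    st_cur <- res$state
    bc_state <- res$bc_state
    times <- c(times, st_cur$t)
    fluxes <- c(fluxes, -res$bflux$inner)
    if (is.na(onset) && identical(res$bc_state$inner, "head")) {
      onset <- st_cur$t
      psi_onset <- st_cur$psi
      break
    }
    dt <- min(dt_used * 1.25, dt_max)
  }
  structure(list(t_onset = onset, r = g$r,
                 psi_onset = psi_onset,
                 theta_onset = if (!is.null(psi_onset))
                   water_content(psi_onset, scn$soil) else NULL,
                 t = times, uptake = fluxes, scn = scn,
                 final = st_cur),
            class = "c11_result")
}
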