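#' Finite-volume soil grids
#'
#' Constructors for the three grid geometries used by the Richards solver.
#' All grids share one representation: cell centres with a vertical
#' coordinate \code{z} (cm, upward, soil surface at 0), cell volumes, and a
#' face list connecting cell pairs with a transmissivity geometry factor
#' \code{area/distance}.  Gravity enters through the difference of the cell
#' centre \code{z} values across a face, so it automatically vanishes on
#' horizontal and radial faces.
#'
#' @param depth column depth (cm)
#' @param n number of cells
#' @param area horizontal cross-section represented by the column (cm^2)
#' @return an object of class \code{soil_grid}
#' @export
soil_grid_vertical <- function(depth, n, area = 1) {
  stopifnot(depth > 0, n >= 2)
  zf <- seq(0, -depth, length.out = n + 1)        # face z, surface first
  zc <- (zf[-1] + zf[-(n + 1)]) / 2
  dz <- depth / n
  structure(list(
    kind = "vertical", n = n, z = zc, vol = rep(area * dz, n),
    face_i = seq_len(n - 1), face_j = 2:n,
    face_geo = rep(area / dz, n - 1),
    boundary = list(
      top = list(cell = 1L, geo = area / (dz / 2), area = area, z_face = 0),
      bottom = list(cell = n, geo = area / (dz / 2), area = area,
                    z_face = -depth)),
    dz = dz, depth = depth, area = area), class = "soil_grid")
}

#' @rdname soil_grid_vertical
#' @param dz_top width of the top (surface) cell (cm)
#' @param dz_max cap on cell width at depth (cm)
#' @param growth geometric growth factor of cell widths downward
#' @export
soil_grid_vertical_graded <- function(depth, dz_top, dz_max = 1,
                                      growth = 1.15, area = 1) {
  stopifnot(depth > 0, dz_top > 0, growth > 1, dz_max >= dz_top)
  w <- numeric(0); s <- 0; wk <- dz_top
  while (s < depth - 1e-12) {
    wk <- min(wk, dz_max, depth - s)
    w <- c(w, wk); s <- s + wk
    wk <- wk * growth
  }
  n <- length(w)
  zf <- c(0, -cumsum(w))
  zc <- (zf[-1] + zf[-(n + 1)]) / 2
  structure(list(
    kind = "vertical", n = n, z = zc, vol = area * w,
    face_i = seq_len(n - 1), face_j = 2:n,
    face_geo = area / diff(-zc),
    boundary = list(
      top = list(cell = 1L, geo = area / (w[1] / 2), area = area, z_face = 0),
      bottom = list(cell = n, geo = area / (w[n] / 2), area = area,
                    z_face = -depth)),
    dz = w, depth = depth, area = area), class = "soil_grid")
}

#' @rdname soil_grid_vertical
#' @param r_root inner (root surface) radius (cm)
#' @param r_out outer radius (cm)
#' @param first_cell width of the innermost cell (cm); cells grow
#'   geometrically outwards so the conductivity drop at the root surface is
#'   resolved
#' @param length axial length represented by the annulus (cm)
#' @export
soil_grid_radial <- function(r_root, r_out, n = 100, first_cell = 1e-3,
                             length = 1) {
  stopifnot(r_out > r_root, r_root > 0, n >= 2)
  # geometric grading: widths w, w*g, ..., summing to r_out - r_root
  span <- r_out - r_root
  g <- stats::uniroot(function(g) {
    if (abs(g - 1) < 1e-12) return(n * first_cell - span)
    first_cell * (g^n - 1) / (g - 1) - span
  }, c(1 + 1e-9, 3), tol = 1e-14)$root
  w <- first_cell * g^(0:(n - 1))
  rf <- r_root + c(0, cumsum(w))
  rf[n + 1] <- r_out
  rc <- (rf[-1] + rf[-(n + 1)]) / 2
  vol <- pi * (rf[-1]^2 - rf[-(n + 1)]^2) * length
  face_r <- rf[2:n]
  structure(list(
    kind = "radial", n = n, z = rep(0, n), r = rc, r_faces = rf, vol = vol,
    face_i = seq_len(n - 1), face_j = 2:n,
    face_geo = 2 * pi * face_r * length / diff(rc),
    boundary = list(
      inner = list(cell = 1L, geo = 2 * pi * rf[1] * length / (rc[1] - rf[1]),
                   area = 2 * pi * rf[1] * length, z_face = 0),
      outer = list(cell = n,
                   geo = 2 * pi * rf[n + 1] * length / (rf[n + 1] - rc[n]),
                   area = 2 * pi * rf[n + 1] * length, z_face = 0)),
    length = length), class = "soil_grid")
}

#' @rdname soil_grid_vertical
#' @param lx,ly,lz domain extents (cm); the soil surface is at z = 0 and the
#'   domain spans \code{[-lz, 0]} vertically
#' @param nx,ny,nz cells per direction
#' @export
soil_grid_box <- function(lx, ly, lz, nx, ny, nz) {
  stopifnot(lx > 0, ly > 0, lz > 0, nx >= 1, ny >= 1, nz >= 1)
  dx <- lx / nx; dy <- ly / ny; dz <- lz / nz
  xc <- -lx / 2 + (seq_len(nx) - 0.5) * dx
  yc <- -ly / 2 + (seq_len(ny) - 0.5) * dy
  zc <- -(seq_len(nz) - 0.5) * dz                 # layer 1 at the surface
  idx <- function(i, j, k) (k - 1L) * nx * ny + (j - 1L) * nx + i
  n <- nx * ny * nz
  cx <- rep(xc, times = ny * nz)
  cy <- rep(rep(yc, each = nx), times = nz)
  cz <- rep(zc, each = nx * ny)
  fi <- integer(0); fj <- integer(0); fg <- numeric(0)
  if (nx > 1) {
    i <- rep(seq_len(nx - 1), times = ny * nz)
    j <- rep(seq_len(ny), each = nx - 1, times = nz)
    k <- rep(seq_len(nz), each = (nx - 1) * ny)
    fi <- c(fi, idx(i, j, k)); fj <- c(fj, idx(i + 1L, j, k))
    fg <- c(fg, rep(dy * dz / dx, (nx - 1) * ny * nz))
  }
  if (ny > 1) {
    i <- rep(seq_len(nx), times = (ny - 1) * nz)
    j <- rep(rep(seq_len(ny - 1), each = nx), times = nz)
    k <- rep(seq_len(nz), each = nx * (ny - 1))
    fi <- c(fi, idx(i, j, k)); fj <- c(fj, idx(i, j + 1L, k))
    fg <- c(fg, rep(dx * dz / dy, nx * (ny - 1) * nz))
  }
  if (nz > 1) {
    i <- rep(seq_len(nx), times = ny * (nz - 1))
    j <- rep(rep(seq_len(ny), each = nx), times = nz - 1)
    k <- rep(seq_len(nz - 1), each = nx * ny)
    fi <- c(fi, idx(i, j, k)); fj <- c(fj, idx(i, j, k + 1L))
    fg <- c(fg, rep(dx * dy / dz, nx * ny * (nz - 1)))
  }
  top_cells <- idx(rep(seq_len(nx), ny), rep(seq_len(ny), each = nx), 1L)
  bot_cells <- idx(rep(seq_len(nx), ny), rep(seq_len(ny), each = nx), nz)
  structure(list(
    kind = "box3d", n = n, nx = nx, ny = ny, nz = nz,
    dx = dx, dy = dy, dz = dz, lx = lx, ly = ly, lz = lz,
    x = cx, y = cy, z = cz, vol = rep(dx * dy * dz, n),
    face_i = fi, face_j = fj, face_geo = fg,
    boundary = list(
      top = list(cell = top_cells, geo = rep(dx * dy / (dz / 2), nx * ny),
                 area = rep(dx * dy, nx * ny), z_face = 0),
      bottom = list(cell = bot_cells, geo = rep(dx * dy / (dz / 2), nx * ny),
                    area = rep(dx * dy, nx * ny), z_face = -lz))),
    class = "soil_grid")
}

#' Soil water state
#'
#' @param grid a \code{soil_grid}
#' @param soil a \code{vg_soil}
#' @param psi initial pressure head (cm): a scalar, a per-cell vector, or a
#'   function of the cell centre \code{z}
#' @param t time (d)
#' @return an object of class \code{soil_state} with per-cell \code{psi},
#'   \code{theta}, the current \code{t} and the per-cell \code{sink}
#'   (cm^3 cm^-3 d^-1, extraction positive)
#' @export
soil_state <- function(grid, soil, psi, t = 0) {
  stopifnot(inherits(grid, "soil_grid"))
  check_soil(soil)
  if (is.function(psi)) psi <- psi(grid$z)
  psi <- rep_len(psi, grid$n)
  structure(list(psi = psi, theta = water_content(psi, soil), t = t,
                 sink = rep(0, grid$n)),
            class = "soil_state")
}

#' Boundary condition specifications
#'
#' Helpers building the boundary spec entries consumed by
#' \code{\link{richards_step}}.  Fluxes are positive into the soil domain.
#' The switching conditions implement the benchmark boundary logic: a
#' prescribed flux that switches to a Dirichlet head when the boundary cell
#' reaches a limiting head, and back when the Dirichlet solution could
#' sustain more than the prescribed flux.  The switch is re-evaluated every
#' step from the current state only, so it is hysteresis-free.
#'
#' @param J boundary flux density (cm/d); positive into the soil for
#'   \code{bc_flux} and \code{bc_switch_influx}, positive out of the soil
#'   for \code{bc_switch_efflux}
#' @param psi prescribed head (cm)
#' @param psi_lim limiting head at which the switch occurs (cm)
#' @return a boundary spec list
#' @export
bc_flux <- function(J) list(mode = "flux", J = J)

#' @rdname bc_flux
#' @export
bc_head <- function(psi) list(mode = "head", psi = psi)

#' @rdname bc_flux
#' @export
bc_free_drainage <- function() list(mode = "free_drainage")

#' @rdname bc_flux
#' @export
bc_no_flux <- function() list(mode = "flux", J = 0)

#' @rdname bc_flux
#' @export
bc_switch_influx <- function(J, psi_lim = 0)
  list(mode = "switch_influx", J = J, psi_lim = psi_lim)

#' @rdname bc_flux
#' @export
bc_switch_efflux <- function(J, psi_lim)
  list(mode = "switch_efflux", J = J, psi_lim = psi_lim)

# resolve a switching bc into plain "flux"/"head" given the current solution.
# dirichlet_flux is the total inflow (cm^3/d) across the face under the
# Dirichlet mode; total_area converts the prescribed flux density.
# Returns list(bc = effective bc, changed = logical)
resolve_switch <- function(bc, eff, psi_cell, dirichlet_flux, total_area) {
  if (bc$mode == "switch_influx") {
    if (eff$mode == "flux") {
      if (any(psi_cell >= bc$psi_lim - 1e-9))
        return(list(bc = list(mode = "head", psi = bc$psi_lim), changed = TRUE))
    } else {
      # under Dirichlet: if the soil could take more than supplied, go back
      if (dirichlet_flux > bc$J * total_area * 1.0000001)
        return(list(bc = list(mode = "flux", J = bc$J), changed = TRUE))
    }
  } else if (bc$mode == "switch_efflux") {
    if (eff$mode == "flux") {
      if (any(psi_cell <= bc$psi_lim + 1e-9))
        return(list(bc = list(mode = "head", psi = bc$psi_lim), changed = TRUE))
    } else {
      if (-dirichlet_flux > bc$J * total_area * 1.0000001)
        return(list(bc = list(mode = "flux", J = -bc$J), changed = TRUE))
    }
  }
  list(bc = eff, changed = FALSE)
}

# dispatch a resolved-bc solve: compiled tridiagonal kernel for the 1D
# geometries, sparse-matrix Picard for the structured 3D grid
solve_resolved <- function(state, grid, soil, eff, dt, sink, L_min = 0,
                           upwind = FALSE) {
  if (grid$kind == "box3d")
    return(picard_solve(state, grid, soil, eff, dt, sink, L_min = L_min))
  side_names <- if (grid$kind == "vertical") c("top", "bottom")
                else c("inner", "outer")
  mode <- integer(2); value <- numeric(2); geo <- numeric(2)
  dzf <- numeric(2); area <- numeric(2)
  for (s in 1:2) {
    b <- grid$boundary[[side_names[s]]]
    bc <- eff[[side_names[s]]]
    if (is.null(bc)) bc <- list(mode = "flux", J = 0)
    area[s] <- b$area
    if (bc$mode == "flux") { mode[s] <- 0L; value[s] <- bc$J * b$area }
    else if (bc$mode == "head") {
      mode[s] <- 1L; value[s] <- bc$psi; geo[s] <- b$geo
      dzf[s] <- b$z_face - grid$z[b$cell]
    } else if (bc$mode == "free_drainage") mode[s] <- 2L
    else stop("unresolved switching bc")
  }
  sp <- c(soil$theta_res, soil$theta_sat, soil$alpha, soil$n, soil$m,
          soil$K_sat, soil$lam)
  out <- .picard1d_cpp(state$psi, state$theta, grid$vol, grid$z,
                       grid$face_geo, sp, mode, value, geo, dzf, area,
                       sink, dt, 1e-3, 1e-7, if (L_min > 0) 600L else 150L,
                       L_min, as.integer(upwind))
  bflux <- stats::setNames(list(out$flux_top, out$flux_bottom), side_names)
  list(psi = out$psi, iter = out$iter, converged = out$converged,
       bflux = bflux, mass_err = out$mass_err,
       extraction = sum(sink * grid$vol))
}

# one implicit-Euler, mixed-form Picard solve at fixed dt and fixed bc modes.
# Returns list(psi, iter, converged, bflux = named actual boundary inflow
# (cm^3/d), mass_err)
picard_solve <- function(state, grid, soil, bcs, dt, sink, L_min = 0) {
  n <- grid$n
  psi_n <- state$psi
  theta_n <- state$theta
  psi <- psi_n
  fi <- grid$face_i; fj <- grid$face_j; fg <- grid$face_geo
  vol <- grid$vol
  z <- grid$z
  tol_psi <- 1e-3
  tol_mass <- 1e-7
  max_iter <- 60L
  omega <- 1       # adaptive under-relaxation stabilizes the sharp-front case
  dmax_prev <- Inf
  for (m in seq_len(max_iter)) {
    K <- conductivity_psi(psi, soil)
    C <- moisture_capacity(psi, soil)
    theta_m <- water_content(psi, soil)
    # chord-slope stabilization plus optional L-scheme floor (consistent:
    # both multiply the iteration increment, which vanishes at convergence)
    dpsi_n <- psi - psi_n
    big <- abs(dpsi_n) > 1e-8
    C[big] <- pmax(C[big], (theta_m[big] - theta_n[big]) / dpsi_n[big])
    C <- pmax(C, L_min)
    Kf <- 0.5 * (K[fi] + K[fj])
    G <- fg * Kf
    diag0 <- C * vol / dt
    if (is.list(sink)) {
      # implicit root-uptake sink: extraction a*psi - b, linear in psi
      diag0 <- diag0 + sink$a * vol
      rhs <- (C * vol / dt) * psi - (theta_m - theta_n) * vol / dt +
        sink$b * vol
    } else {
      rhs <- diag0 * psi - (theta_m - theta_n) * vol / dt - sink * vol
    }
    # gravity across internal faces: flux i->j includes G*(z_i - z_j)
    gz <- G * (z[fi] - z[fj])
    rhs <- rhs - tapply_add(numeric(n), fi, gz) + tapply_add(numeric(n), fj, gz)
    ii <- c(seq_len(n), fi, fj, fi, fj)
    jj <- c(seq_len(n), fj, fi, fi, fj)
    xx <- c(diag0, -G, -G, G, G)
    # boundary terms
    bnames <- names(bcs)
    for (bn in bnames) {
      bc <- bcs[[bn]]
      b <- grid$boundary[[bn]]
      cells <- b$cell
      if (bc$mode == "flux") {
        rhs[cells] <- rhs[cells] + bc$J * b$area
      } else if (bc$mode == "free_drainage") {
        # unit total-head gradient: downward flux K(theta_cell) out
        rhs[cells] <- rhs[cells] - K[cells] * b$area
      } else if (bc$mode == "head") {
        Kb <- 0.5 * (K[cells] + conductivity_psi(rep(bc$psi, length(cells)),
                                                 soil))
        Gb <- b$geo * Kb
        ii <- c(ii, cells); jj <- c(jj, cells); xx <- c(xx, Gb)
        rhs[cells] <- rhs[cells] + Gb * (bc$psi + (b$z_face - z[cells]))
      } else stop("unresolved switching bc in picard_solve")
    }
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
    # the system is symmetric positive definite: supernodal Cholesky
    psi_new <- as.numeric(Matrix::solve(
      Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE,
                       super = TRUE), rhs,
      system = "A"))
    dmax <- max(abs(psi_new - psi))
    if (dmax > 0.9 * dmax_prev) omega <- max(0.2, omega * 0.5)
    else omega <- min(1, omega * 1.4)
    psi <- psi + omega * (psi_new - psi)
    dmax_prev <- dmax
    if (dmax < tol_psi || m %% 5 == 0) {
      # accept on the nonlinear mass residual (the conservation contract):
      # on flat retention curves the psi increment alone can stay large
      # while the discrete equations are already satisfied
      res <- mass_residual(psi, theta_n, grid, soil, bcs, dt, sink)
      if (res$rel_err < tol_mass || m == max_iter)
        return(list(psi = psi, iter = m, converged = res$rel_err < 1e-7,
                    bflux = res$bflux, mass_err = res$rel_err,
                    extraction = res$extraction))
    }
  }
  list(psi = psi, iter = max_iter, converged = FALSE, bflux = NULL,
       mass_err = NA_real_)
}

# add values v into vector acc at integer indices id (with repeats)
tapply_add <- function(acc, id, v) {
  s <- rowsum(v, id)
  acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s[, 1]
  acc
}

# evaluate the discrete mass balance of a candidate solution
mass_residual <- function(psi, theta_n, grid, soil, bcs, dt, sink) {
  n <- grid$n
  K <- conductivity_psi(psi, soil)
  theta <- water_content(psi, soil)
  fi <- grid$face_i; fj <- grid$face_j
  Kf <- 0.5 * (K[fi] + K[fj])
  G <- grid$face_geo * Kf
  Fij <- G * ((psi[fi] + grid$z[fi]) - (psi[fj] + grid$z[fj]))
  div <- numeric(n)
  div <- tapply_add(div, fi, -Fij)
  div <- tapply_add(div, fj, Fij)
  bflux <- list()
  for (bn in names(bcs)) {
    bc <- bcs[[bn]]
    b <- grid$boundary[[bn]]
    cells <- b$cell
    if (bc$mode == "flux") {
      f <- bc$J * b$area
    } else if (bc$mode == "free_drainage") {
      f <- -K[cells] * b$area
    } else if (bc$mode == "head") {
      Kb <- 0.5 * (K[cells] + conductivity_psi(rep(bc$psi, length(cells)),
                                               soil))
      f <- b$geo * Kb * ((bc$psi + b$z_face) - (psi[cells] + grid$z[cells]))
    } else stop("unresolved switching bc")
    div[cells] <- div[cells] + f
    bflux[[bn]] <- sum(f)
  }
  ext <- if (is.list(sink)) sink$a * psi - sink$b else sink
  resid <- (theta - theta_n) * grid$vol / dt - div + ext * grid$vol
  wref <- max(sum(theta * grid$vol), 1e-12)
  list(rel_err = sum(abs(resid)) * dt / wref, bflux = bflux,
       cell_resid = resid, extraction = sum(ext * grid$vol))
}

#' One implicit Richards step
#'
#' Advances a \code{soil_state} by \code{dt} with a cell-centred
#' finite-volume, implicit-Euler discretization of the mixed-form Richards
#' equation, solved by modified-Picard iteration (inter-cell conductivity by
#' arithmetic mean).  Switching boundary conditions are resolved within the
#' step: the step is recomputed whenever the active mode changes, so the
#' final state is consistent with the mode it was computed under.
#'
#' @param state a \code{soil_state}
#' @param grid a \code{soil_grid}
#' @param soil a \code{vg_soil}
#' @param bcs named list of boundary specs (see \code{\link{bc_flux}});
#'   names must match the grid's boundary faces; missing faces are no-flux
#' @param dt time step (d)
#' @param sink per-cell extraction (cm^3 cm^-3 d^-1), positive removes water
#' @param bc_state optional list of previously active modes for switching
#'   conditions (carried between steps purely as a solve starting point)
#' @param face_k inter-cell conductivity scheme: \code{"arithmetic"} mean
#'   (default) or \code{"upwind"} (total-head upstream weighting; first
#'   order but robust on soils whose conductivity is extremely sensitive
#'   near saturation, such as the benchmark clay)
#' @return a list with the advanced \code{state}, \code{bflux} (named list
#'   of actual boundary inflow rates, cm^3/d), \code{mass_err} (relative
#'   step mass-balance error), \code{iter}, \code{bc_state}
#' @export
richards_step <- function(state, grid, soil, bcs, dt, sink = NULL,
                          bc_state = NULL, face_k = "arithmetic") {
  stopifnot(inherits(state, "soil_state"), dt > 0)
  if (is.null(sink)) sink <- state$sink
  if (is.list(sink)) {
    stopifnot(grid$kind == "box3d")
    sink$a <- rep_len(sink$a, grid$n); sink$b <- rep_len(sink$b, grid$n)
  } else sink <- rep_len(sink, grid$n)
  # effective (resolved) bcs: start from previous modes where available
  eff <- list()
  for (bn in names(bcs)) {
    bc <- bcs[[bn]]
    if (bc$mode == "switch_influx") {
      eff[[bn]] <- if (!is.null(bc_state[[bn]]) &&
                       bc_state[[bn]] == "head")
        list(mode = "head", psi = bc$psi_lim) else list(mode = "flux", J = bc$J)
    } else if (bc$mode == "switch_efflux") {
      eff[[bn]] <- if (!is.null(bc_state[[bn]]) &&
                       bc_state[[bn]] == "head")
        list(mode = "head", psi = bc$psi_lim)
      else list(mode = "flux", J = -bc$J)
    } else eff[[bn]] <- bc
  }
  # escalating storage-floor (L-scheme) retries before giving up on this dt:
  # the floored iteration is consistent (the floor multiplies the converged
  # increment, which vanishes) but contractive on degenerate fronts
  Cref <- max(moisture_capacity(seq(-1, min(state$psi) - 1, length.out = 200),
                                soil))
  upw <- identical(face_k, "upwind")
  if (upw && grid$kind == "box3d")
    stop("upwind face conductivity is only available on 1D grids")
  for (sweep in 1:4) {
    sol <- NULL
    for (L in c(0, 0.3 * Cref, 3 * Cref)) {
      sol <- solve_resolved(state, grid, soil, eff, dt, sink, L_min = L,
                            upwind = upw)
      if (sol$converged) break
    }
    if (!sol$converged) return(list(converged = FALSE))
    changed <- FALSE
    for (bn in names(bcs)) {
      bc <- bcs[[bn]]
      if (!(bc$mode %in% c("switch_influx", "switch_efflux"))) next
      b <- grid$boundary[[bn]]
      r <- resolve_switch(bc, eff[[bn]], sol$psi[b$cell], sol$bflux[[bn]],
                          sum(b$area))
      if (r$changed) { eff[[bn]] <- r$bc; changed <- TRUE }
    }
    if (!changed) break
  }
  new_state <- structure(list(psi = sol$psi,
                              theta = water_content(sol$psi, soil),
                              t = state$t + dt,
                              sink = if (is.list(sink))
                                sink$a * sol$psi - sink$b else sink),
                         class = "soil_state")
  modes <- lapply(eff, function(e) e$mode)
  list(state = new_state, bflux = sol$bflux, mass_err = sol$mass_err,
       iter = sol$iter, bc_state = modes, converged = TRUE,
       extraction = sol$extraction)
}

#' Run the Richards solver with adaptive stepping
#'
#' Repeatedly calls \code{\link{richards_step}} with an adaptive step size
#' (growth factor 1.25 on success, halving on non-convergence) and collects
#' states at the requested output times.
#'
#' @inheritParams richards_step
#' @param t_end final time (d)
#' @param out_times times at which states are recorded (d)
#' @param dt0 initial step (d)
#' @param dt_max step cap (d)
#' @param dt_min smallest admissible step before a hard error (d)
#' @param monitor optional function called after every accepted step with
#'   the step result (used by the benchmarks to record boundary fluxes)
#' @return a list with \code{states} (one \code{soil_state} per output
#'   time), \code{cum_bflux} (named cumulative boundary inflow volumes,
#'   cm^3), \code{max_mass_err}, and \code{flux_series} (data frame of step
#'   times and boundary inflow rates)
#' @export
richards_run <- function(state, grid, soil, bcs, t_end,
                         out_times = t_end, dt0 = 1e-4, dt_max = 0.01,
                         dt_min = 1e-10, sink = NULL, monitor = NULL,
                         face_k = "arithmetic") {
  out_times <- sort(out_times)
  stopifnot(all(out_times > state$t), t_end >= max(out_times))
  states <- vector("list", length(out_times))
  dt <- dt0
  bc_state <- NULL
  cum <- list()
  cum_sink <- 0
  max_err <- 0
  flux_rows <- list()
  next_out <- 1L
  while (state$t < t_end - 1e-12) {
    target <- if (next_out <= length(out_times)) out_times[next_out] else t_end
    dt_try <- min(dt, target - state$t)
    res <- richards_step(state, grid, soil, bcs, dt_try, sink = sink,
                         bc_state = bc_state, face_k = face_k)
    if (!res$converged) {
      dt <- dt_try / 2
      if (dt < dt_min) stop("Richards solver failed to converge at t = ",
                            state$t, " with dt = ", dt)
      next
    }
    state <- res$state
    bc_state <- res$bc_state
    max_err <- max(max_err, res$mass_err)
    for (bn in names(res$bflux))
      cum[[bn]] <- (if (is.null(cum[[bn]])) 0 else cum[[bn]]) +
        res$bflux[[bn]] * dt_try
    cum_sink <- cum_sink + res$extraction * dt_try
    flux_rows[[length(flux_rows) + 1L]] <-
      c(t = state$t, unlist(res$bflux), dt = dt_try)
    if (!is.null(monitor)) monitor(res)
    if (next_out <= length(out_times) &&
        abs(state$t - out_times[next_out]) < 1e-10) {
      states[[next_out]] <- state
      next_out <- next_out + 1L
    }
    dt <- min(dt_try * 1.25, dt_max)
  }
  flux_series <- as.data.frame(do.call(rbind, flux_rows))
  list(states = states, cum_bflux = cum, cum_sink = cum_sink,
       max_mass_err = max_err, flux_series = flux_series, final = state)
}
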