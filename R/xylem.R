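#' Root hydraulic properties
#'
#' Radial conductivity \code{k_r} (1/d: flow per root surface area per unit
#' head difference) and axial conductance \code{k_x} (cm^3/d: flow per unit
#' head gradient) — either constants, or piecewise-linear lookup tables in
#' root age per root type, clamped outside the tabulated range.
#'
#' @param k_r constant radial conductivity, or a named list of data frames
#'   (one per type) with columns \code{age} (d) and \code{value}
#' @param k_x constant axial conductance, or a named list like \code{k_r}
#' @return an object of class \code{root_hydraulics}
#' @export
root_hydraulics <- function(k_r, k_x) {
  chk <- function(x, what) {
    if (is.numeric(x)) {
      if (x < 0) stop(what, " must be non-negative")
    } else if (is.list(x)) {
      for (nm in names(x)) {
        tb <- x[[nm]]
        stopifnot(all(c("age", "value") %in% names(tb)))
        if (is.unsorted(tb$age)) stop(what, " table for type '", nm,
                                      "' must have increasing age")
        if (any(tb$value < 0)) stop(what, " must be non-negative")
      }
    } else stop(what, " must be numeric or a list of tables")
  }
  chk(k_r, "k_r"); chk(k_x, "k_x")
  structure(list(k_r = k_r, k_x = k_x), class = "root_hydraulics")
}

#' Look up root hydraulic properties at an age and type
#'
#' @param props a \code{root_hydraulics}
#' @param age root segment age (d), vectorized
#' @param type root type label (used for table-valued properties)
#' @return a list with vectors \code{k_r} and \code{k_x}
#' @export
props_at <- function(props, age, type = "tap") {
  stopifnot(inherits(props, "root_hydraulics"), all(age >= 0))
  look <- function(x, what) {
    if (is.numeric(x)) return(rep(x, length(age)))
    tb <- x[[type]]
    if (is.null(tb)) stop("unknown root type '", type, "' for ", what)
    stats::approx(tb$age, tb$value, xout = age, rule = 2)$y
  }
  list(k_r = look(props$k_r, "k_r"), k_x = look(props$k_x, "k_x"))
}

#' Closed-form xylem pressure in a single root
#'
#' Analytical solution of the axial-radial flow balance
#' \eqn{2 r \pi k_r (\psi_s - \psi_x) = -k_x \psi_x''} for constant
#' properties, a Dirichlet collar head \eqn{\psi_0} at \eqn{\zeta = 0} and
#' zero axial flow at the tip \eqn{\zeta = l}:
#' \deqn{\psi_x(\zeta) = \psi_s + (\psi_0 - \psi_s)
#'   \frac{\cosh(c(l - \zeta))}{\cosh(c\,l)}, \qquad
#'   c = \sqrt{2 r_{root} \pi k_r / k_x}.}
#'
#' @param zeta position along the root from the collar (cm), vectorized
#' @param l root length (cm)
#' @param r_root root radius (cm)
#' @param k_r radial conductivity (1/d)
#' @param k_x axial conductance (cm^3/d)
#' @param psi_s uniform soil pressure head (cm)
#' @param psi_0 collar pressure head (cm)
#' @return xylem pressure head at \code{zeta} (cm)
#' @export
single_root_psi <- function(zeta, l, r_root, k_r, k_x, psi_s, psi_0) {
  stopifnot(l > 0, r_root > 0, k_r >= 0, k_x > 0,
            all(zeta >= -1e-12), all(zeta <= l + 1e-12))
  cc <- sqrt(2 * r_root * pi * k_r / k_x)
  psi_s + (psi_0 - psi_s) * cosh(cc * (l - zeta)) / cosh(cc * l)
}

#' Collar boundary condition for the xylem solver
#'
#' Either a prescribed collar head, or a prescribed collar outflow
#' (transpiration) with a critical head: the flux is honoured while the
#' resulting collar head stays above \code{psi_crit}, otherwise the collar
#' is pinned at \code{psi_crit} and the actual (reduced) outflow reported.
#'
#' @param psi collar pressure head (cm) for the head mode
#' @param Q_pot potential collar outflow (cm^3/d) for the flux mode
#' @param psi_crit critical collar head (cm), required with \code{Q_pot}
#' @return a list of class \code{collar_bc}
#' @export
collar_head <- function(psi) {
  structure(list(mode = "head", psi = psi), class = "collar_bc")
}

#' @rdname collar_head
#' @export
collar_flux <- function(Q_pot, psi_crit = -15290) {
  structure(list(mode = "flux", Q_pot = Q_pot, psi_crit = psi_crit),
            class = "collar_bc")
}

#' Solve water flow in a root network
#'
#' Doussan-type sparse solve of the xylem pressure at every node of a
#' (discretized) root system.  Each segment contributes an axial conductance
#' \code{k_x / l} between its end nodes and a radial conductance
#' \code{2 pi r l k_r} to the soil, lumped half to each end node
#' (trapezoidal lumping, second-order in the segment length).  The collar
#' condition is either a pinned head or a prescribed outflow with automatic
#' switching to the critical head (solve in flux mode; if the collar head
#' falls below \code{psi_crit}, re-solve pinned and report the actual
#' outflow).
#'
#' @param rs a \code{root_system}
#' @param props a \code{root_hydraulics}
#' @param psi_s soil pressure head seen by each segment (cm): a scalar or a
#'   per-segment vector
#' @param collar a \code{collar_bc}
#' @param t current time (d), used for segment ages with table props
#' @param gravity if \code{TRUE}, the axial driving force is the total head
#'   \eqn{\psi_x + z} (coupled benchmarks); if \code{FALSE} only the
#'   pressure head gradient drives axial flow (static xylem benchmarks)
#' @return a list of class \code{xylem_solution}: \code{psi_x} per node,
#'   \code{Q_ax} axial flow per segment (cm^3/d, positive toward the tip),
#'   \code{Q_rad} radial inflow per segment (cm^3/d, positive into the
#'   root), \code{collar_flow} (cm^3/d, positive out of the plant),
#'   \code{collar_psi}, \code{stressed}, and the per-segment \code{k_r},
#'   \code{k_x} used
#' @export
solve_xylem <- function(rs, props, psi_s, collar, t = NULL,
                        gravity = FALSE) {
  stopifnot(inherits(rs, "root_system"), inherits(collar, "collar_bc"))
  nd <- rs$nodes; sg <- rs$segments
  n <- nrow(nd)
  if (nrow(sg) == 0) stop("root system has no segments")
  id2row <- match(seq_len(max(nd$id)), nd$id)
  ip <- id2row[sg$prox]; jp <- id2row[sg$dist]
  len <- segment_lengths(rs)
  psi_s <- rep_len(psi_s, nrow(sg))
  seg_type <- rs$roots$type[match(sg$root_id, rs$roots$root_id)]
  seg_type[is.na(seg_type)] <- "tap"
  age <- if (is.null(t)) rep(0, nrow(sg))
         else pmax(t - (nd$ctime[ip] + nd$ctime[jp]) / 2, 0)
  kr <- numeric(nrow(sg)); kx <- numeric(nrow(sg))
  for (ty in unique(seg_type)) {
    sel <- seg_type == ty
    pa <- props_at(props, age[sel], ty)
    kr[sel] <- pa$k_r; kx[sel] <- pa$k_x
  }
  if (any(kx <= 0)) stop("k_x must be positive on every segment")
  rad <- (nd$radius[ip] + nd$radius[jp]) / 2
  c_ax <- kx / len
  c_rad <- 2 * pi * rad * len * kr
  zz <- if (gravity) nd$z else rep(0, n)

  assemble_solve <- function(mode, value) {
    ii <- c(ip, jp, ip, jp, seq_len(n))
    jj <- c(jp, ip, ip, jp, seq_len(n))
    xx <- c(-c_ax, -c_ax, c_ax, c_ax, rep(0, n))
    diag_rad <- numeric(n)
    rhs <- numeric(n)
    # radial exchange lumped half-half onto end nodes
    for (endix in list(ip, jp)) {
      add <- rowsum(c_rad / 2, endix)
      rows <- as.integer(rownames(add))
      diag_rad[rows] <- diag_rad[rows] + add[, 1]
      addr <- rowsum(c_rad / 2 * psi_s, endix)
      rhs[rows] <- rhs[rows] + addr[, 1]
    }
    # gravity in the axial term: flux prox->dist = c_ax*((h_p) - (h_d)),
    # h = psi + z
    gz <- c_ax * (zz[ip] - zz[jp])
    gr <- numeric(n)
    s1 <- rowsum(gz, ip); gr[as.integer(rownames(s1))] <-
      gr[as.integer(rownames(s1))] - s1[, 1]
    s2 <- rowsum(gz, jp); gr[as.integer(rownames(s2))] <-
      gr[as.integer(rownames(s2))] + s2[, 1]
    rhs <- rhs + gr
    A <- Matrix::sparseMatrix(i = ii, j = jj,
                              x = xx + c(rep(0, 4 * nrow(sg)), diag_rad),
                              dims = c(n, n))
    collar_row <- id2row[1L]
    if (mode == "head") {
      # pin by row replacement
      A[collar_row, ] <- 0
      A[collar_row, collar_row] <- 1
      rhs[collar_row] <- value
    } else {
      rhs[collar_row] <- rhs[collar_row] - value   # outflow Q at the collar
    }
    as.numeric(Matrix::solve(A, rhs))
  }

  stressed <- FALSE
  if (collar$mode == "head") {
    psi_x <- assemble_solve("head", collar$psi)
  } else {
    psi_x <- assemble_solve("flux", collar$Q_pot)
    if (psi_x[id2row[1L]] < collar$psi_crit) {
      stressed <- TRUE
      psi_x <- assemble_solve("head", collar$psi_crit)
    }
  }
  h <- psi_x + zz
  Q_ax <- c_ax * (h[ip] - h[jp])     # positive toward the tip
  psi_mid <- (psi_x[ip] + psi_x[jp]) / 2
  Q_rad <- c_rad * (psi_s - psi_mid)
  collar_flow <- sum(Q_rad)
  structure(list(psi_x = psi_x, Q_ax = Q_ax, Q_rad = Q_rad,
                 collar_flow = collar_flow,
                 collar_psi = psi_x[id2row[1L]],
                 stressed = stressed, k_r = kr, k_x = kx,
                 c_rad = c_rad, psi_x_mid = psi_mid,
                 node_id = nd$id),
            class = "xylem_solution")
}

#' Build the M3.1 single-root system
#'
#' A straight vertical root of the benchmark geometry (default 50 cm, 0.02
#' cm radius), discretized at the requested resolution, collar at the top.
#'
#' @param l root length (cm)
#' @param dz segment length (cm)
#' @param r_root root radius (cm)
#' @param z0 z of the collar (cm)
#' @return a \code{root_system}
#' @export
single_root_system <- function(l = 50, dz = 0.1, r_root = 0.02, z0 = 0) {
  n <- ceiling(l / dz)
  z <- z0 - seq(0, l, length.out = n + 1)
  nodes <- data.frame(id = seq_len(n + 1), x = 0, y = 0, z = z,
                      ctime = 0, radius = r_root)
  segments <- data.frame(prox = seq_len(n), dist = 2:(n + 1),
                         root_id = 1L, order = 0L)
  roots <- data.frame(root_id = 1L, parent_root = NA_integer_,
                      parent_node = 1L, order = 0L, type = "tap")
  root_system(nodes, segments, roots)
}
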