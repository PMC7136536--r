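#' Traveling-wave infiltration profile
#'
#' Semi-analytic reference solution for constant-rate infiltration into a
#' uniformly dry column.  The water-content profile moves downward as a
#' traveling wave whose front speed is
#' \eqn{v = [K(\theta_{sur})-K(\theta_i)]/(\theta_{sur}-\theta_i)} and whose
#' shape is the displacement
#' \deqn{\Delta\eta(\theta) = (\theta_{sur}-\theta_i)\int_\theta^{\theta_a}
#'   \frac{D_w(u)\,du}{[K(\theta_{sur})-K(\theta_i)](u-\theta_i) -
#'   [K(u)-K(\theta_i)](\theta_{sur}-\theta_i)}}
#' relative to the reference content \eqn{\theta_a = (\theta_{sur}+\theta_i)/2},
#' which travels at depth \eqn{v\,t}.
#'
#' Because the solution is implicit in \eqn{\theta}, the profile is returned
#' as sampled \code{(theta, depth)} pairs on a fixed grid of water contents
#' strictly between \code{theta_i} and \code{theta_sur}; monotonicity makes
#' interpolation onto any depth grid safe.  The diffusivity diverges at
#' saturation, so contents are truncated 1e-6 below \code{theta_sat}.
#'
#' @param soil a \code{vg_soil}
#' @param theta_i initial water content (-)
#' @param theta_sur surface water content (-), greater than \code{theta_i}
#' @param t time (d)
#' @param n_out number of sampled water contents
#' @param n_quad size of the internal quadrature grid
#' @param eps_frac fractional distance to \code{theta_i}/\code{theta_sur} at
#'   which sampling stops (the profile tail and surface value are asymptotes)
#' @param cum_infiltration optional cumulative infiltration (cm of water) up
#'   to time \code{t}.  When supplied, the profile is positioned so that its
#'   stored water \eqn{\int_0^\infty(\theta-\theta_i)dz} equals this amount
#'   (profile clipped at the soil surface), anchoring the asymptotic wave
#'   through the mass balance; when omitted the reference content travels at
#'   exactly \eqn{v\,t}.  For a constant-flux scenario
#'   \code{cum_infiltration = J * t} is exact.
#' @return a list of class \code{traveling_wave} with fields \code{thetas},
#'   \code{depths} (cm, positive downward), \code{t}, \code{theta_sur},
#'   \code{theta_i}, \code{theta_a} and the front speed \code{v} (cm/d).
#' @export
infiltration_profile <- function(soil, theta_i, theta_sur, t,
                                 n_out = 400L, n_quad = 20000L,
                                 eps_frac = 1e-4, cum_infiltration = NULL) {
  check_soil(soil)
  if (theta_sur <= theta_i) stop("theta_sur must exceed theta_i")
  if (t <= 0) stop("t must be positive")
  ts <- min(theta_sur, soil$theta_sat - 1e-6)
  ti <- max(theta_i, soil$theta_res + 1e-9)
  theta_a <- (theta_sur + theta_i) / 2
  Ki <- hydraulic_conductivity(ti, soil)
  Ks <- hydraulic_conductivity(theta_sur, soil)
  v <- (Ks - Ki) / (theta_sur - theta_i)

  eps <- eps_frac * (ts - ti)
  # Chebyshev-type clustering toward both asymptotic ends
  u <- (1 - cos(seq(0, pi, length.out = n_quad))) / 2
  th_fine <- (ti + eps) + u * ((ts - eps) - (ti + eps))
  Dw <- water_diffusivity(th_fine, soil)
  K <- hydraulic_conductivity(th_fine, soil)
  G <- (Ks - Ki) * (th_fine - ti) - (K - Ki) * (theta_sur - theta_i)
  f <- Dw / G
  cumI <- as.vector(pracma::cumtrapz(th_fine, f))
  Ca <- stats::approx(th_fine, cumI, xout = theta_a)$y
  thetas <- seq(ti + eps, ts - eps, length.out = n_out)
  Cth <- stats::approx(th_fine, cumI, xout = thetas)$y
  deta <- (theta_sur - theta_i) * (Ca - Cth)
  z_a <- v * t
  if (!is.null(cum_infiltration)) {
    # anchor the reference-content depth so the stored water matches
    deta_f <- (theta_sur - theta_i) *
      (Ca - stats::approx(th_fine, cumI, xout = th_fine)$y)
    stored <- function(za) pracma::trapz(th_fine, pmax(za + deta_f, 0))
    lo <- 0; hi <- max(2 * z_a, 10)
    while (stored(hi) < cum_infiltration) hi <- hi * 2
    z_a <- stats::uniroot(function(za) stored(za) - cum_infiltration,
                          c(lo, hi), tol = 1e-10)$root
  }
  depths <- z_a + deta
  structure(list(thetas = thetas, depths = depths, t = t,
                 theta_sur = theta_sur, theta_i = theta_i,
                 theta_a = theta_a, v = v),
            class = "traveling_wave")
}

#' Evaluate a traveling-wave profile on a depth grid
#'
#' @param profile a \code{traveling_wave}
#' @param depths depths (cm, positive downward)
#' @return water contents at the requested depths; the surface value is used
#'   above the sampled profile and the initial value below it.
#' @export
eval_traveling_wave <- function(profile, depths) {
  ord <- order(profile$depths)
  stats::approx(profile$depths[ord], profile$thetas[ord], xout = depths,
                yleft = profile$theta_sur, yright = profile$theta_i,
                rule = 2)$y
}

#' Stage-two evaporation constants (desorptivity)
#'
#' Computes the constants of the two-stage evaporation solution.  Stage one
#' evaporates at the potential rate; stage two is supply-limited and decays
#' as \eqn{t^{-1/2}} with desorptivity
#' \eqn{S_w = (\theta_i - \theta_{sur})\sqrt{4\mu\int_0^1 D_w(\Theta)d\Theta}},
#' where \eqn{\Theta = |(\theta-\theta_{sur})/(\theta_i-\theta_{sur})|} is the
#' normalized water content.  The moment integrals
#' \eqn{\beta_e = [\int\Theta D_w d\Theta / \int D_w d\Theta]^2} and
#' \eqn{\alpha_e = \int(1-\beta_e\Theta)^2 D_w d\Theta / \int D_w d\Theta}
#' are reported alongside.  The coefficient \eqn{\mu} is obtained from the
#' exact Boltzmann similarity solution of the drying half-space (see
#' \code{\link{similarity_desorptivity}}); for constant diffusivity it equals
#' \eqn{1/\pi}.
#'
#' Given a potential rate the switch time satisfies
#' \eqn{t' = S_w^2/(4 J_{pot}^2)} and \eqn{t_{pot} = S_w^2/(2 J_{pot}^2)},
#' so that the stage-two flux is continuous at \eqn{t_{pot}}.
#'
#' @param soil a \code{vg_soil}
#' @param theta_i initial (wet) water content (-)
#' @param theta_sur surface (dry) water content (-), below \code{theta_i}
#' @param J_pot optional potential evaporation rate (cm/d); if given,
#'   \code{t_pot} and \code{t_prime} are filled in
#' @param n_quad quadrature grid size for the moment integrals
#' @return a list of class \code{desorptivity} with fields \code{S_w},
#'   \code{mu}, \code{alpha_e}, \code{beta_e}, \code{D_int} (the normalized
#'   diffusivity integral, cm^2/d), and when \code{J_pot} is supplied
#'   \code{J_pot}, \code{t_pot}, \code{t_prime} (d).
#' @export
desorptivity <- function(soil, theta_i, theta_sur, J_pot = NULL,
                         n_quad = 20000L) {
  check_soil(soil)
  if (theta_sur >= theta_i) stop("drying requires theta_sur < theta_i")
  if (theta_sur <= soil$theta_res || theta_i >= soil$theta_sat)
    stop("water contents must lie strictly inside the retention range")
  Th <- seq(1e-6, 1 - 1e-6, length.out = n_quad)
  th <- theta_sur + Th * (theta_i - theta_sur)
  Dw <- water_diffusivity(th, soil)
  D_int <- pracma::trapz(Th, Dw)
  beta_e <- (pracma::trapz(Th, Th * Dw) / D_int)^2
  alpha_e <- pracma::trapz(Th, (1 - beta_e * Th)^2 * Dw) / D_int
  S_w <- similarity_desorptivity(function(x) water_diffusivity(x, soil),
                                 theta_sur, theta_i)
  mu <- (S_w / (theta_i - theta_sur))^2 / (4 * D_int)
  out <- list(S_w = S_w, mu = mu, alpha_e = alpha_e, beta_e = beta_e,
              D_int = D_int, theta_i = theta_i, theta_sur = theta_sur)
  if (!is.null(J_pot)) {
    out$J_pot <- J_pot
    out$t_prime <- S_w^2 / (4 * J_pot^2)
    out$t_pot <- S_w^2 / (2 * J_pot^2)
  }
  structure(out, class = "desorptivity")
}

#' Desorptivity from the Boltzmann similarity solution
#'
#' Solves the similarity form of the horizontal (gravity-free) drying
#' problem: with \eqn{\phi = z/\sqrt{t}} and
#' \eqn{w(\theta) = \int_\theta^{\theta_i}\phi\,d\vartheta}, the profile
#' satisfies the boundary-value problem \eqn{w'' = -2D_w(\theta)/w} with
#' \eqn{w'(\theta_{sur}) = 0} and \eqn{w(\theta_i) = 0}; the desorptivity is
#' \eqn{S_w = w(\theta_{sur})}.  Solved by bisection shooting with a
#' fixed-step midpoint integrator.
#'
#' @param Dfun vectorized diffusivity function of theta (cm^2/d)
#' @param theta_sur dry surface water content
#' @param theta_i initial water content, greater than \code{theta_sur}
#' @param ngrid number of integration steps
#' @return desorptivity (cm d^-0.5)
#' @export
similarity_desorptivity <- function(Dfun, theta_sur, theta_i, ngrid = 4000L) {
  eps <- (theta_i - theta_sur) * 1e-8
  th <- seq(theta_sur, theta_i - eps, length.out = ngrid + 1)
  h <- th[2] - th[1]
  Dmid <- Dfun(pmin(pmax((th[-1] + th[-(ngrid + 1)]) / 2,
                         theta_sur + eps), theta_i - eps))
  shoot <- function(S) {
    w <- S; v <- 0
    for (i in seq_len(ngrid)) {
      if (w <= 0) return(-(ngrid - i + 1) * h)
      a1 <- -2 * Dmid[i] / w
      wm <- w + 0.5 * h * v
      vm <- v + 0.5 * h * a1
      if (wm <= 0) return(-(ngrid - i + 1) * h)
      w <- w + h * vm
      v <- v + h * (-2 * Dmid[i] / wm)
    }
    w
  }
  hi <- 2 * (theta_i - theta_sur) *
    sqrt(max(Dfun((theta_sur + theta_i) / 2), 1e-12))
  lo <- 1e-10
  while (shoot(hi) < 0) hi <- hi * 2
  while (shoot(lo) > 0) lo <- lo / 2
  stats::uniroot(shoot, c(lo, hi), tol = 1e-13)$root
}

#' Two-stage evaporation flux
#'
#' \eqn{J(t) = J_{pot}} for \eqn{t < t_{pot}} and
#' \eqn{J(t) = S_w / (2\sqrt{t' + t - t_{pot}})} afterwards; continuous at
#' \eqn{t_{pot}} by construction of \eqn{t'}.
#'
#' @param consts a \code{desorptivity} object carrying \code{J_pot}
#' @param t time (d), vectorized
#' @return evaporative flux (cm/d), monotone non-increasing
#' @export
evaporation_rate <- function(consts, t) {
  if (is.null(consts$J_pot)) stop("consts must carry J_pot (see desorptivity)")
  stopifnot(all(t >= 0))
  out <- rep(consts$J_pot, length(t))
  s2 <- t >= consts$t_pot
  out[s2] <- consts$S_w / (2 * sqrt(consts$t_prime + t[s2] - consts$t_pot))
  out
}

#' Single-root radial uptake scenario
#'
#' Geometry and fluxes for the steady-rate single-root water uptake problem:
#' a root of radius \code{r_root} at the centre of a soil cylinder of radius
#' \code{r_out}, extracting \code{q_root} (cm^3 per cm^2 root surface per
#' day) with flux \code{q_out} across the outer boundary.
#'
#' @param soil a \code{vg_soil} or soil name from the catalogue
#' @param r_root root radius (cm)
#' @param r_out outer radius (cm)
#' @param q_root uptake flux at the root surface (cm/d)
#' @param q_out flux at the outer boundary (cm/d), default 0
#' @param psi_lim limiting pressure head at the root surface (cm)
#' @param psi_i initial pressure head (cm)
#' @return a list of class \code{radial_scenario}
#' @export
radial_scenario <- function(soil, r_root = 0.02, r_out = 0.6, q_root = 0.1,
                            q_out = 0, psi_lim = -15000, psi_i = -100) {
  if (is.character(soil)) soil <- soil_catalogue(soil)
  check_soil(soil)
  if (!(r_out > r_root && r_root > 0)) stop("require r_out > r_root > 0")
  structure(list(soil = soil, r_root = r_root, r_out = r_out,
                 rho = r_out / r_root, q_root = q_root, q_out = q_out,
                 psi_lim = psi_lim, psi_i = psi_i),
            class = "radial_scenario")
}

#' Steady-rate radial profile of the matric flux potential
#'
#' Evaluates the steady-rate solution of the linearized (Kirchhoff
#' transformed) radial flow problem around a single root.  In the
#' non-stressed regime the profile is driven by the prescribed uptake flux
#' \code{q_root}; in the stressed regime the root-surface potential is pinned
#' at \code{Phi(psi_lim)} and the profile is driven by the boundary
#' potentials.
#'
#' @param scn a \code{radial_scenario}
#' @param phi_rout matric flux potential at the outer radius (cm^2/d)
#' @param r radii at which to evaluate (cm), within
#'   \code{[r_root, r_out]}
#' @param phi_rroot root-surface matric flux potential (cm^2/d); if
#'   \code{NULL} the non-stressed flux-driven profile is used
#' @return matric flux potential at \code{r} (cm^2/d)
#' @export
radial_mfp_profile <- function(scn, phi_rout, r, phi_rroot = NULL) {
  stopifnot(inherits(scn, "radial_scenario"))
  if (any(r < scn$r_root - 1e-12 | r > scn$r_out + 1e-12))
    stop("r outside [r_root, r_out]")
  rho <- scn$rho
  if (is.null(phi_rroot)) {
    phi_rout +
      (scn$q_root * scn$r_root - scn$q_out * scn$r_out) *
      ((r^2 / scn$r_root^2) / (2 * (1 - rho^2)) +
         rho^2 / (1 - rho^2) * (log(scn$r_out / r) - 0.5)) +
      scn$q_out * scn$r_out * log(r / scn$r_out)
  } else {
    num <- r^2 / scn$r_root^2 - 1 + 2 * rho^2 * log(scn$r_root / r)
    den <- rho^2 - 1 + 2 * rho^2 * log(1 / rho)
    (phi_rout - phi_rroot + scn$q_out * scn$r_out * log(1 / rho)) *
      num / den +
      scn$q_out * scn$r_out * log(r / scn$r_root) + phi_rroot
  }
}

#' Onset of root water stress for the steady-rate radial solution
#'
#' Finds the non-stressed profile whose root-surface pressure head has just
#' reached \code{psi_lim}, and the time at which it is reached.  The time
#' follows from a water balance: the water remaining per cm root length in
#' the hollow soil cylinder is \eqn{V = 2\pi\int_{r_{root}}^{r_{out}} r\,
#' \theta(r)\,dr}, the initial volume is
#' \eqn{V_i = \pi(r_{out}^2 - r_{root}^2)\theta_i}, and with a constant
#' uptake rate the onset time is
#' \eqn{t = (V_i - V) / (2\pi r_{root} q_{root})}.
#'
#' @param scn a \code{radial_scenario}
#' @param n_r number of radial sample points for profile and volume integral
#' @return a list with \code{t_onset} (d), \code{r} (cm), \code{phi}
#'   (cm^2/d), \code{psi} (cm), \code{theta} (-), \code{phi_rout},
#'   \code{V}, \code{V_i} (cm^3 per cm root length)
#' @export
stress_onset <- function(scn, n_r = 200L) {
  stopifnot(inherits(scn, "radial_scenario"))
  soil <- scn$soil
  theta_i <- water_content(scn$psi_i, soil)
  if (scn$psi_i <= scn$psi_lim) {
    r <- seq(scn$r_root, scn$r_out, length.out = n_r)
    return(list(t_onset = 0, r = r,
                phi = rep(matric_flux_potential(scn$psi_i, soil, scn$psi_lim),
                          n_r),
                psi = rep(scn$psi_i, n_r), theta = rep(theta_i, n_r),
                phi_rout = matric_flux_potential(scn$psi_i, soil, scn$psi_lim),
                V = pi * (scn$r_out^2 - scn$r_root^2) * theta_i,
                V_i = pi * (scn$r_out^2 - scn$r_root^2) * theta_i))
  }
  phi_lim <- matric_flux_potential(scn$psi_lim, soil, scn$psi_lim)  # zero
  # bracket term of the flux-driven profile evaluated at the root surface
  rho <- scn$rho
  B <- (1 / (2 * (1 - rho^2)) +
          rho^2 / (1 - rho^2) * (log(rho) - 0.5))
  phi_rout <- phi_lim - (scn$q_root * scn$r_root - scn$q_out * scn$r_out) * B -
    scn$q_out * scn$r_out * log(scn$r_root / scn$r_out)
  # log-spaced radii resolve the steep gradient at the root surface
  r <- exp(seq(log(scn$r_root), log(scn$r_out), length.out = n_r))
  phi <- radial_mfp_profile(scn, phi_rout, r)
  psi <- invert_mfp(pmax(phi, 0), soil, scn$psi_lim)
  theta <- water_content(psi, soil)
  V <- 2 * pi * pracma::trapz(r, r * theta)
  V_i <- pi * (scn$r_out^2 - scn$r_root^2) * theta_i
  t_onset <- (V_i - V) / (2 * pi * scn$r_root * scn$q_root)
  list(t_onset = t_onset, r = r, phi = phi, psi = psi, theta = theta,
       phi_rout = phi_rout, V = V, V_i = V_i)
}
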