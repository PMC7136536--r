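#' Van Genuchten--Mualem soil hydraulic parameter set
#'
#' Constructs a soil parameter object for the van Genuchten retention curve
#' combined with the Mualem conductivity model.  All quantities follow the
#' package-wide unit convention: lengths and pressure heads in cm (of water
#' column), time in days, so that conductivities are in cm/d.  Pressure heads
#' are negative in unsaturated soil; psi >= 0 is treated as saturated.
#'
#' @param theta_res residual volumetric water content (-)
#' @param theta_sat saturated volumetric water content (-)
#' @param alpha inverse air-entry pressure head (1/cm)
#' @param n retention shape parameter (-), must exceed 1
#' @param K_sat saturated hydraulic conductivity (cm/d)
#' @param lam Mualem tortuosity exponent (-)
#' @param name optional soil label
#' @return an object of class \code{vg_soil}; the Mualem constraint
#'   \code{m = 1 - 1/n} is stored alongside the parameters.
#' @examples
#' loam <- vg_soil(0.08, 0.43, 0.04, 1.6, 50, 0.5, "loam")
#' water_content(-659.8, loam)  # about 0.129
#' @export
vg_soil <- function(theta_res, theta_sat, alpha, n, K_sat, lam = 0.5,
                    name = "soil") {
  stopifnot(is.numeric(theta_res), is.numeric(theta_sat), is.numeric(alpha),
            is.numeric(n), is.numeric(K_sat), is.numeric(lam))
  if (!(theta_res >= 0 && theta_res < theta_sat && theta_sat <= 1))
    stop("require 0 <= theta_res < theta_sat <= 1")
  if (alpha <= 0) stop("alpha must be positive")
  if (n <= 1) stop("n must exceed 1")
  if (K_sat <= 0) stop("K_sat must be positive")
  structure(list(theta_res = theta_res, theta_sat = theta_sat, alpha = alpha,
                 n = n, m = 1 - 1 / n, K_sat = K_sat, lam = lam,
                 name = name),
            class = "vg_soil")
}

#' @export
print.vg_soil <- function(x, ...) {
  cat(sprintf(
    "<vg_soil '%s'> theta_res=%.3f theta_sat=%.3f alpha=%.3g n=%.3g K_sat=%.3g lam=%.3g\n",
    x$name, x$theta_res, x$theta_sat, x$alpha, x$n, x$K_sat, x$lam))
  invisible(x)
}

#' Catalogue of benchmark soils
#'
#' The three benchmark soils (sand, loam, clay) with their van Genuchten
#' parameters, shipped as a plain-text catalogue in
#' \code{inst/extdata/soil_catalogue.csv}.
#'
#' @param name one of \code{"sand"}, \code{"loam"}, \code{"clay"}; if
#'   missing, the full catalogue is returned as a data frame.
#' @return a \code{vg_soil} object, or a data frame listing all soils.
#' @export
soil_catalogue <- function(name) {
  path <- system.file("extdata", "soil_catalogue.csv", package = "rootbench",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (missing(name)) return(tab)
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L)
    stop("unknown soil '", name, "'; available: ",
         paste(tab$name, collapse = ", "))
  vg_soil(row$theta_res, row$theta_sat, row$alpha, row$n, row$K_sat, row$lam,
          row$name)
}

check_soil <- function(soil) {
  if (!inherits(soil, "vg_soil")) stop("'soil' must be a vg_soil object")
  soil
}

#' Water retention curve
#'
#' Volumetric water content as a function of pressure head,
#' \eqn{\theta(\psi) = \theta_r + (\theta_s-\theta_r)[1+(\alpha|\psi|)^n]^{-m}}
#' for \eqn{\psi < 0} and \eqn{\theta_s} at or above saturation.
#'
#' @param psi pressure head (cm), vectorized
#' @param soil a \code{vg_soil}
#' @return volumetric water content (-)
#' @export
water_content <- function(psi, soil) {
  check_soil(soil)
  stopifnot(all(is.finite(psi)))
  se <- ifelse(psi < 0, (1 + (soil$alpha * abs(psi))^soil$n)^(-soil$m), 1)
  soil$theta_res + (soil$theta_sat - soil$theta_res) * se
}

#' Inverse retention curve
#'
#' Pressure head corresponding to a water content; the analytical inverse of
#' \code{\link{water_content}}.  \code{pressure_head(theta_sat)} is 0.
#'
#' @param theta volumetric water content, in \code{(theta_res, theta_sat]}
#' @param soil a \code{vg_soil}
#' @return pressure head (cm), non-positive
#' @export
pressure_head <- function(theta, soil) {
  check_soil(soil)
  if (any(theta <= soil$theta_res | theta > soil$theta_sat + 1e-12))
    stop("theta outside (theta_res, theta_sat]")
  theta <- pmin(theta, soil$theta_sat)
  se <- (theta - soil$theta_res) / (soil$theta_sat - soil$theta_res)
  ifelse(se >= 1, 0, -(se^(-1 / soil$m) - 1)^(1 / soil$n) / soil$alpha)
}

#' Effective saturation
#'
#' @param theta volumetric water content
#' @param soil a \code{vg_soil}
#' @return \eqn{S_e = (\theta-\theta_r)/(\theta_s-\theta_r)}
#' @export
effective_saturation <- function(theta, soil) {
  check_soil(soil)
  (theta - soil$theta_res) / (soil$theta_sat - soil$theta_res)
}

#' Mualem hydraulic conductivity
#'
#' \eqn{K = K_{sat} S_e^{\lambda} [1-(1-S_e^{1/m})^m]^2} as a function of
#' water content.
#'
#' @param theta volumetric water content, in \code{[theta_res, theta_sat]}
#' @param soil a \code{vg_soil}
#' @return hydraulic conductivity (cm/d)
#' @export
hydraulic_conductivity <- function(theta, soil) {
  check_soil(soil)
  if (any(theta < soil$theta_res - 1e-12 | theta > soil$theta_sat + 1e-12))
    stop("theta outside [theta_res, theta_sat]")
  se <- pmin(pmax(effective_saturation(theta, soil), 0), 1)
  soil$K_sat * se^soil$lam * (1 - (1 - se^(1 / soil$m))^soil$m)^2
}

#' Hydraulic conductivity as a function of pressure head
#'
#' @param psi pressure head (cm)
#' @param soil a \code{vg_soil}
#' @return hydraulic conductivity (cm/d)
#' @export
conductivity_psi <- function(psi, soil) {
  hydraulic_conductivity(water_content(psi, soil), soil)
}

#' Specific moisture capacity
#'
#' Analytic derivative \eqn{C(\psi) = d\theta/d\psi} of the retention curve,
#' used by the mixed-form Richards solver.  Zero at and above saturation.
#'
#' @param psi pressure head (cm)
#' @param soil a \code{vg_soil}
#' @return capacity (1/cm), non-negative
#' @export
moisture_capacity <- function(psi, soil) {
  check_soil(soil)
  a <- soil$alpha; n <- soil$n; m <- soil$m
  dth <- soil$theta_sat - soil$theta_res
  out <- numeric(length(psi))
  neg <- psi < 0
  h <- abs(psi[neg])
  out[neg] <- dth * m * n * a^n * h^(n - 1) * (1 + (a * h)^n)^(-m - 1)
  out
}

#' Soil water diffusivity
#'
#' \eqn{D_w(\theta) = K(\theta)\, d\psi/d\theta}, the diffusivity of the
#' water-content form of the Richards equation.  Diverges at saturation, so
#' evaluation requires \code{theta} strictly inside
#' \code{(theta_res, theta_sat)}.
#'
#' @param theta volumetric water content, strictly inside the retention range
#' @param soil a \code{vg_soil}
#' @return diffusivity (cm^2/d)
#' @export
water_diffusivity <- function(theta, soil) {
  check_soil(soil)
  if (any(theta <= soil$theta_res | theta >= soil$theta_sat))
    stop("diffusivity requires theta strictly inside (theta_res, theta_sat)")
  psi <- pressure_head(theta, soil)
  hydraulic_conductivity(theta, soil) / moisture_capacity(psi, soil)
}

#' Matric flux potential
#'
#' Kirchhoff transform \eqn{\Phi(\psi) = \int_{\psi_{lower}}^{\psi} K(h)\,dh}
#' by adaptive quadrature.  The default lower limit is the permanent wilting
#' head -15000 cm.
#'
#' @param psi upper integration limit (cm), \code{psi_lower <= psi <= 0}
#' @param soil a \code{vg_soil}
#' @param psi_lower lower integration limit (cm)
#' @return matric flux potential (cm^2/d), vectorized over \code{psi}
#' @export
matric_flux_potential <- function(psi, soil, psi_lower = -15000) {
  check_soil(soil)
  if (any(psi < psi_lower)) stop("psi below psi_lower")
  if (any(psi > 0)) stop("psi must be non-positive")
  vapply(psi, function(p) {
    if (p == psi_lower) return(0)
    stats::integrate(function(h) conductivity_psi(h, soil), psi_lower, p,
                     rel.tol = 1e-10, abs.tol = 1e-8,
                     subdivisions = 500L)$value
  }, numeric(1))
}

#' Invert the matric flux potential
#'
#' Finds the pressure head whose matric flux potential equals \code{phi},
#' by monotone root bracketing on \code{\link{matric_flux_potential}}.
#'
#' @param phi matric flux potential (cm^2/d), vectorized
#' @param soil a \code{vg_soil}
#' @param psi_lower lower limit of the transform (cm)
#' @return pressure head (cm)
#' @export
invert_mfp <- function(phi, soil, psi_lower = -15000) {
  check_soil(soil)
  phimax <- matric_flux_potential(0, soil, psi_lower)
  vapply(phi, function(p) {
    if (p <= 0) return(psi_lower)
    if (p >= phimax) return(0)
    stats::uniroot(function(psi) matric_flux_potential(psi, soil, psi_lower) - p,
                   lower = psi_lower, upper = 0, tol = 1e-8)$root
  }, numeric(1))
}

#' Convert pressure in MPa to head in cm of water
#'
#' Uses water density 1000 kg/m^3 and g = 9.81 m/s^2, so that -1.5 MPa is
#' about -15290 cm, the conventional wilting point head.
#'
#' @param mpa pressure (MPa)
#' @return equivalent pressure head (cm)
#' @export
mpa_to_head <- function(mpa) {
  mpa * 1e6 / (1000 * 9.81) * 100
}

#' Convert head in cm of water to pressure in MPa
#' @param head pressure head (cm)
#' @return pressure (MPa)
#' @export
head_to_mpa <- function(head) {
  head / 100 * 1000 * 9.81 / 1e6
}
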