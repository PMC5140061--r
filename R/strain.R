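#' Elongation strain-rate field over the cross-section
#'
#' First-order (in dt) strain rate of every surface fiber of a curved
#' cylindrical segment whose curvature magnitude and direction are changing
#' while the median line elongates at rate `Edot`. It is the exact
#' linearization of the finite surface-fiber strain: with
#' `k = C*R` and fiber length `Ls(phi) = L0*(1 - k*cos(phi - psi_c))`,
#'
#'   epsdot(phi) = Edot - (dk/dt * cos(phi - psi_c) +
#'                  k * dpsi_dt * sin(phi - psi_c)) / (1 - k*cos(phi - psi_c))
#'
#' The two contributions dominate in orthogonal planes: at
#' `phi = psi_c, psi_c + pi` only the curvature-rate term acts, at
#' `phi = psi_c +/- pi/2` only the direction-rate term. A fiber on the
#' concave side grows slower than the median while curvature increases.
#'
#' @param seg list with `C` (1/mm) and `psi_c` (rad) of the segment.
#' @param R organ radius (mm).
#' @param dCR_dt rate of change of the dimensionless curvature `C*R` (1/s).
#' @param dpsi_dt rate of change of the curvature direction (rad/s).
#' @param Edot median elongation rate (1/s).
#' @param phis cross-section angles to sample (rad), covering (-pi, pi].
#' @return an object of class `strain_profile`: list with `phis`, `rates`,
#'   and the median rate `Edot`.
#' @export
strain_rate_field <- function(seg, R, dCR_dt, dpsi_dt, Edot, phis) {
  seg <- as.list(seg)
  k <- seg$C * R
  if (k >= 1) {
    stop("invalid geometry: C*R >= 1 (inner surface fiber length nonpositive)")
  }
  u <- phis - seg$psi_c
  rates <- Edot - (dCR_dt * cos(u) + k * dpsi_dt * sin(u)) / (1 - k * cos(u))
  structure(list(phis = phis, rates = rates, Edot = Edot),
            class = "strain_profile")
}

#' Differential growth in and orthogonal to the plane of curvature
#'
#' Directed differential growth at cross-section angle `phi` is defined as
#' the excess elongation rate of the far side over the near side, normalized
#' by twice the median rate:
#'
#'   Delta(phi) = (epsdot(phi + pi) - epsdot(phi)) / (2 * Edot)
#'
#' so `Delta(phi) = 1` means all growth occurs opposite `phi` (the organ
#' bends toward `phi`) and `Delta = 0` means symmetric growth in that plane.
#' The pair returned evaluates this at `phi = psi_c` (in-plane component
#' `Delta_par`, driving the curvature magnitude) and at `phi = psi_c + pi/2`
#' (orthogonal component `Delta_perp`, driving the curvature direction).
#' With the strain-rate field of [strain_rate_field()] the evolution laws
#' `d(CR)/dt = Delta_par * Edot * (1 - (CR)^2)` and
#' `dpsi_c/dt = Delta_perp * Edot / (CR)` hold exactly.
#'
#' @param profile a `strain_profile` sampled on a grid covering a full turn.
#' @param psi_c curvature direction (rad) at which to project.
#' @param Edot median elongation rate (1/s); must be > 0.
#' @return named numeric vector `c(par = Delta_par, perp = Delta_perp)`.
#' @export
differential_growth_pair <- function(profile, psi_c, Edot = profile$Edot) {
  if (Edot <= 0) stop("Edot must be > 0: differential growth is undefined")
  at <- function(phi) interp_periodic(profile$phis, profile$rates, phi)
  dpar  <- (at(psi_c + pi) - at(psi_c)) / (2 * Edot)
  dperp <- (at(psi_c + 3 * pi / 2) - at(psi_c + pi / 2)) / (2 * Edot)
  c(par = dpar, perp = dperp)
}

# Linear interpolation of a 2*pi-periodic sampled function.
interp_periodic <- function(x, y, xout) {
  x0 <- min(x)
  xr <- (xout - x0) %% (2 * pi) + x0
  xx <- c(x, x[which.min(x)] + 2 * pi)
  yy <- c(y, y[which.min(x)])
  ord <- order(xx)
  stats::approx(xx[ord], yy[ord], xout = xr, rule = 2)$y
}

#' Project the principal differential growth onto the curvature frame
#'
#' The differential-growth field is characterized by its magnitude
#' `delta_max` and its principal direction `psi_g` (the cross-section angle
#' the organ is driven to bend toward). Its components in the plane of
#' curvature and orthogonal to it are the cosine and sine projections onto
#' the current curvature direction `psi_c`:
#' `(delta_max * cos(psi_g - psi_c), delta_max * sin(psi_g - psi_c))`.
#'
#' @param delta_max magnitude of the differential growth (>= 0).
#' @param psi_g principal direction of differential growth (rad).
#' @param psi_c current curvature direction (rad).
#' @return named numeric vector `c(par = , perp = )`.
#' @examples
#' project_growth(1, pi / 3, 0)
#' @export
project_growth <- function(delta_max, psi_g, psi_c) {
  stopifnot(delta_max >= 0)
  c(par = delta_max * cos(psi_g - psi_c),
    perp = delta_max * sin(psi_g - psi_c))
}
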