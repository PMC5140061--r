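# Time evolution of the curvature state.
#
# The evolution laws for curvature magnitude and direction are singular at
# C = 0 (the direction equation carries a 1/(CR) prefactor), so stepping is
# done on the dimensionless curvature vector
#   kappa = C*R * (cos psi_c, sin psi_c),
# for which the same dynamics are the regular linear system
#   dkappa/dt = delta_edot * (cos psi_g, sin psi_g) - (gamma*Edot/R) * kappa.
# The drive term is the differential-growth forcing (projections onto the
# curvature frame recombine into a fixed vector along psi_g); the damping
# term is proprioception, which acts along -kappa and is therefore purely
# in-plane. (C, psi_c) are decoded views of kappa.

# Rate of the curvature vector. kappa: n x 2 matrix; other args scalars or
# length-n vectors. With keep_quadratic the component of the rate parallel
# to kappa (the in-plane part) is multiplied by (1 - |kappa|^2), the exact
# finite-curvature prefactor of the magnitude equation.
kappa_rate <- function(kappa, edot, delta_edot, psi_g, gamma, R,
                       keep_quadratic = FALSE) {
  rate <- cbind(delta_edot * cos(psi_g), delta_edot * sin(psi_g)) -
    (gamma * edot / R) * kappa
  if (keep_quadratic) {
    k2 <- rowSums(kappa ^ 2)
    nz <- k2 > 0
    if (any(nz)) {
      khat <- kappa[nz, , drop = FALSE] / sqrt(k2[nz])
      par_mag <- rowSums(rate[nz, , drop = FALSE] * khat)
      # subtract the quadratic part of the parallel component
      rate[nz, ] <- rate[nz, , drop = FALSE] -
        (par_mag * k2[nz]) * khat
    }
  }
  rate
}

#' Advance one material segment by one explicit Euler step
#'
#' Updates the curvature vector under the differential-growth drive and
#' proprioceptive damping, and compounds the rest length by
#' `(1 + Edot * dt)`. Pure median elongation (`delta_edot = 0`, `gamma = 0`)
#' leaves curvature magnitude and direction untouched while the segment
#' elongates (passive drift). With the driver aligned to the curvature
#' direction, `C*R` grows linearly at rate `delta_edot`
#' (or as `tanh(delta_edot * t)` when `keep_quadratic = TRUE`).
#'
#' @param seg list with `rest_length` (mm), `C` (1/mm), `psi_c` (rad).
#' @param R organ radius (mm).
#' @param edot median elongation rate (1/s).
#' @param delta_edot differential-growth drive, the rate it imposes on
#'   `C*R` (1/s); >= 0.
#' @param psi_g principal direction of differential growth (rad).
#' @param gamma proprioceptive gain (mm); the damping rate is
#'   `gamma * edot / R`.
#' @param dt time step (s).
#' @param keep_quadratic retain the `(1 - (CR)^2)` prefactor on the
#'   in-plane component (negligible in the `C*R << 1` regime).
#' @return updated segment list with fields `rest_length`, `C`, `psi_c`.
#' @export
step_segment <- function(seg, R, edot, delta_edot, psi_g, gamma = 0, dt,
                         keep_quadratic = FALSE) {
  stopifnot(dt > 0, delta_edot >= 0, edot >= 0)
  seg <- as.list(seg)
  k <- seg$C * R
  kap <- matrix(c(k * cos(seg$psi_c), k * sin(seg$psi_c)), 1, 2)
  kap <- kap + dt * kappa_rate(kap, edot, delta_edot, psi_g, gamma, R,
                               keep_quadratic)
  knew <- sqrt(sum(kap ^ 2))
  if (knew >= 1) {
    stop("geometry error: C*R >= 1 after step; reduce dt or add proprioception")
  }
  list(
    rest_length = seg$rest_length * (1 + edot * dt),
    C = knew / R,
    psi_c = if (knew > 0) atan2(kap[2], kap[1]) else seg$psi_c
  )
}

#' Advance the whole organ by one time step
#'
#' Every material segment is stepped with the driver evaluated at the
#' segment's current mid-abscissa. Because segments are material
#' (co-moving), the advective part of the material derivative is realized
#' implicitly: abscissas are recomputed from the elongated rest lengths, so
#' each element is pushed apically by the cumulative elongation below it.
#' Segments below the growth zone (`s < L - L_gz`) receive zero elongation
#' and zero differential growth, freezing their curvature and direction.
#'
#' @param organ an [organ_state()].
#' @param driver a [growth_driver()] (its internal oscillator state is used
#'   as-is; advance it separately with [advance_driver()]).
#' @param dt time step (s).
#' @param method `"euler"` (default, first order) or `"midpoint"` (second
#'   order; driver evaluated at the half step).
#' @param keep_quadratic see [step_segment()].
#' @return the organ at `time + dt`.
#' @export
advance_organ <- function(organ, driver, dt, method = c("euler", "midpoint"),
                          keep_quadratic = FALSE) {
  method <- match.arg(method)
  stopifnot(dt > 0)
  s_mid <- abscissa(organ) + organ$rest_length / 2
  L <- organ_length(organ)
  R <- organ$radius
  dv <- evaluate_driver(driver, s_mid, organ$time, L = L)
  grow <- s_mid >= (L - driver$L_gz)
  edot <- dv$edot * grow
  dd <- dv$delta_edot * grow

  if (method == "euler") {
    kap <- organ$kappa + dt * kappa_rate(organ$kappa, edot, dd, dv$psi_g,
                                         driver$gamma, R, keep_quadratic)
  } else {
    half <- organ$kappa + (dt / 2) * kappa_rate(organ$kappa, edot, dd,
                                                dv$psi_g, driver$gamma, R,
                                                keep_quadratic)
    dh <- advance_driver(driver, dt / 2)
    dvh <- evaluate_driver(dh, s_mid, organ$time + dt / 2, L = L)
    ddh <- dvh$delta_edot * grow
    edh <- dvh$edot * grow
    kap <- organ$kappa + dt * kappa_rate(half, edh, ddh, dvh$psi_g,
                                         driver$gamma, R, keep_quadratic)
  }
  kmag <- sqrt(rowSums(kap ^ 2))
  if (any(kmag >= 1)) {
    stop(sprintf(
      "geometry error at t = %g s: C*R >= 1 in %d segment(s); reduce dt or add proprioception",
      organ$time, sum(kmag >= 1)))
  }
  organ$kappa <- kap
  organ$psi_memory <- ifelse(kmag > 0, atan2(kap[, 2], kap[, 1]),
                             organ$psi_memory)
  organ$rest_length <- organ$rest_length * (1 + edot * dt)
  organ$time <- organ$time + dt
  organ
}

#' Growth-induced velocity profile along the organ
#'
#' Velocity of the material point at abscissa `s` is the integral of the
#' median elongation rate from the base, discretized as a cumulative sum
#' over segments. The basal boundary is clamped (velocity 0).
#'
#' @param organ an [organ_state()].
#' @param edot per-segment median elongation rate (1/s), recycled.
#' @return velocity (mm/s) at each segment boundary (length `n + 1`).
#' @export
growth_velocity <- function(organ, edot) {
  edot <- rep_len(edot, length(organ$rest_length))
  c(0, cumsum(edot * organ$rest_length))
}
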