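#' Differential-growth driver programs
#'
#' A growth driver prescribes, at any abscissa `s` and time `t`, the median
#' elongation rate `Edot`, the differential-growth drive `delta_edot` (the
#' rate it imposes on the dimensionless curvature `C*R`), and the principal
#' direction of differential growth `psi_g`. Rules:
#'
#' * `constant` — fixed `psi_g = psi_g0`.
#' * `uniform_rotation` — `psi_g = psi_g0 + omega * t` (the endogenous
#'   oscillator rotating at constant angular frequency).
#' * `rate_modulated` — `dpsi_g/dt = omega * (1 + a * cos(2 * psi_g))`,
#'   integrated internally alongside the organ; the rotation slows near
#'   `psi_g = +/- pi/2`, producing an ellipse.
#' * `amplitude_modulated` — `psi_g = psi_g0 + omega * t` with drive
#'   `delta_edot * (1 + a * cos(2 * psi_g))`; the other ellipse mechanism,
#'   whose pattern is rotated by pi/2 from the rate-modulated one.
#' * `two_zone` — the organ is split at fraction `zone_frac[1]` of its
#'   length; each part runs its own uniform rotation (`zone_omega`) and
#'   drive (`zone_delta_edot`), producing epi-/hypotrochoid tip patterns.
#'
#' @param rule driver rule, see above.
#' @param delta_edot differential-growth drive (1/s), the imposed rate of
#'   `C*R`.
#' @param edot median elongation rate (1/s); 0 freezes organ length.
#' @param omega angular frequency of `psi_g` (rad/s).
#' @param a modulation depth, `|a| < 1`.
#' @param psi_g0 initial / constant direction (rad).
#' @param zone_frac,zone_omega,zone_delta_edot two-zone split fractions
#'   (summing to 1), angular frequencies and drives, base part first.
#' @param gamma proprioceptive gain (mm); damping rate is `gamma * edot / R`.
#' @param L_gz growth-zone length (mm) measured from the apex; `Inf` means
#'   the whole organ grows.
#' @return an object of class `growth_driver`.
#' @export
growth_driver <- function(rule = c("constant", "uniform_rotation",
                                   "rate_modulated", "amplitude_modulated",
                                   "two_zone"),
                          delta_edot = 0, edot = 0, omega = 0, a = 0,
                          psi_g0 = 0, zone_frac = c(0.5, 0.5),
                          zone_omega = NULL, zone_delta_edot = NULL,
                          gamma = 0, L_gz = Inf) {
  rule <- match.arg(rule)
  stopifnot(delta_edot >= 0, edot >= 0, gamma >= 0, L_gz > 0)
  if (rule %in% c("rate_modulated", "amplitude_modulated") && abs(a) >= 1) {
    stop("modulation depth |a| must be < 1")
  }
  if (rule == "two_zone") {
    stopifnot(length(zone_frac) == 2, length(zone_omega) == 2,
              length(zone_delta_edot) == 2)
    if (abs(sum(zone_frac) - 1) > 1e-12) stop("zone fractions must sum to 1")
  }
  structure(list(rule = rule, delta_edot = delta_edot, edot = edot,
                 omega = omega, a = a, psi_g0 = psi_g0,
                 zone_frac = zone_frac, zone_omega = zone_omega,
                 zone_delta_edot = zone_delta_edot,
                 gamma = gamma, L_gz = L_gz,
                 psi_g_state = psi_g0),
            class = "growth_driver")
}

#' @export
print.growth_driver <- function(x, ...) {
  cat("<growth_driver>", x$rule, "\n")
  cat("  delta_edot:", format(x$delta_edot), "1/s  edot:", format(x$edot),
      "1/s  gamma:", format(x$gamma), "mm  L_gz:", format(x$L_gz), "mm\n")
  if (x$rule == "two_zone") {
    cat("  zones:", paste(format(x$zone_frac), collapse = "/"),
        " omega:", paste(format(x$zone_omega), collapse = ", "), "rad/s\n")
  } else if (x$rule != "constant") {
    cat("  omega:", format(x$omega), "rad/s  a:", format(x$a), "\n")
  }
  invisible(x)
}

#' Evaluate a driver at abscissas `s` and time `t`
#'
#' @param driver a [growth_driver()].
#' @param s abscissas (mm), vector.
#' @param t time (s).
#' @param L current organ length (mm); required for `two_zone`.
#' @return list with vectors `edot`, `delta_edot`, `psi_g` (recycled to
#'   `length(s)`).
#' @export
evaluate_driver <- function(driver, s, t, L = NULL) {
  n <- length(s)
  edot <- rep_len(driver$edot, n)
  switch(driver$rule,
    constant = list(edot = edot,
                    delta_edot = rep_len(driver$delta_edot, n),
                    psi_g = rep_len(driver$psi_g0, n)),
    uniform_rotation = list(edot = edot,
                            delta_edot = rep_len(driver$delta_edot, n),
                            psi_g = rep_len(driver$psi_g0 + driver$omega * t,
                                            n)),
    rate_modulated = list(edot = edot,
                          delta_edot = rep_len(driver$delta_edot, n),
                          psi_g = rep_len(driver$psi_g_state, n)),
    amplitude_modulated = {
      psi <- driver$psi_g0 + driver$omega * t
      list(edot = edot,
           delta_edot = rep_len(driver$delta_edot * (1 + driver$a *
                                                       cos(2 * psi)), n),
           psi_g = rep_len(psi, n))
    },
    two_zone = {
      if (is.null(L)) stop("two_zone driver needs the current organ length L")
      base_part <- s <= driver$zone_frac[1] * L
      list(edot = edot,
           delta_edot = ifelse(base_part, driver$zone_delta_edot[1],
                               driver$zone_delta_edot[2]),
           psi_g = driver$psi_g0 +
             ifelse(base_part, driver$zone_omega[1], driver$zone_omega[2]) * t)
    },
    stop("unknown driver rule: ", driver$rule)
  )
}

#' Advance a driver's internal oscillator state
#'
#' Only `rate_modulated` carries state: the rule
#' `dpsi_g/dt = omega * (1 + a * cos(2 * psi_g))` is integrated with the
#' same time step as the organ, using an explicit midpoint update so the
#' oscillator's period carries no first-order step bias.
#'
#' @param driver a [growth_driver()].
#' @param dt time step (s).
#' @return the driver with updated state.
#' @export
advance_driver <- function(driver, dt) {
  if (driver$rule == "rate_modulated") {
    f <- function(p) driver$omega * (1 + driver$a * cos(2 * p))
    p <- driver$psi_g_state
    driver$psi_g_state <- p + dt * f(p + dt / 2 * f(p))
  }
  driver
}

#' Exact rotation period of the rate-modulated oscillator
#'
#' The rule `dpsi_g/dt = omega0 * (1 + a * cos(2 * psi_g))` has the
#' closed-form full-rotation period `2 * pi / (omega0 * sqrt(1 - a^2))`.
#'
#' @param omega0 base angular frequency (rad/s).
#' @param a modulation depth, `|a| < 1`.
#' @return period (s).
#' @examples
#' rate_modulated_period(2 * pi / 13800, 0.5)
#' @export
rate_modulated_period <- function(omega0, a) {
  if (abs(a) >= 1) stop("modulation depth |a| must be < 1")
  2 * pi / (abs(omega0) * sqrt(1 - a ^ 2))
}

#' Characteristic (slow) period of a driver
#'
#' @param driver a [growth_driver()].
#' @return period (s); `Inf` for a constant driver.
#' @export
driver_period <- function(driver) {
  switch(driver$rule,
    constant = Inf,
    uniform_rotation = 2 * pi / abs(driver$omega),
    amplitude_modulated = 2 * pi / abs(driver$omega),
    rate_modulated = rate_modulated_period(driver$omega, driver$a),
    two_zone = 2 * pi / min(abs(driver$zone_omega))
  )
}

#' Preset drivers reproducing the simulated pattern zoo
#'
#' Registry keyed by the interactive simulator digits:
#' \describe{
#'   \item{"0"}{ellipse, rate-modulated rotation (`a = 0.5`).}
#'   \item{"1"}{ellipse, amplitude-modulated drive (`a = 0.5`); its major
#'     axis is rotated pi/2 from preset "0".}
#'   \item{"2"}{constant direction: curvature aligns with `psi_g`.}
#'   \item{"3"}{circle with proprioception: a single stable orbit centered
#'     on the base, independent of initial conditions.}
#'   \item{"4"}{circle with whole-organ elongation: a growth spiral with
#'     unchanged per-turn period.}
#'   \item{"5"}{circle with a subapical growth zone: basal segments freeze
#'     into a stored helix.}
#'   \item{"circle"}{plain rotating driver, no growth, no proprioception.}
#'   \item{"epitrochoid"}{two-zone driver, apical part at `+6 * omega0` and
#'     five-fold drive.}
#'   \item{"hypotrochoid"}{same with apical part at `-6 * omega0`.}
#' }
#'
#' Default scales emulate an Arabidopsis-like organ: rotation period
#' 230 min (`omega0 = 2 * pi / 13800` rad/s), drive sized for a steady
#' dimensionless curvature amplitude `kappa_amp = 0.01` (so `C * L` stays
#' small and the tip stays in the small-curvature regime), radius 0.5 mm.
#'
#' @param key preset key (character or digit).
#' @param omega0 base angular frequency (rad/s).
#' @param kappa_amp target steady amplitude of `C*R` (dimensionless).
#' @param R organ radius (mm), used to size proprioceptive gain.
#' @param edot elongation rate override (1/s); presets "3"-"5" have
#'   nonzero defaults.
#' @return a [growth_driver()].
#' @export
preset_driver <- function(key, omega0 = 2 * pi / 13800, kappa_amp = 0.01,
                          R = 0.5, edot = NULL) {
  key <- as.character(key)
  dd <- kappa_amp * omega0
  pick <- function(default) if (is.null(edot)) default else edot
  switch(key,
    "0" = , "S4" = growth_driver("rate_modulated", delta_edot = dd,
                                 omega = omega0, a = 0.5,
                                 edot = pick(0)),
    "1" = , "S5" = growth_driver("amplitude_modulated", delta_edot = dd,
                                 omega = omega0, a = 0.5, edot = pick(0)),
    "2" = , "S2" = , "constant" = growth_driver("constant", delta_edot = dd,
                                                psi_g0 = 0, edot = pick(0)),
    "3" = {
      ed <- pick(1e-6)
      # damping rate gamma*edot/R set equal to omega0; drive sized so the
      # steady amplitude delta_edot / sqrt(omega^2 + damping^2) = kappa_amp
      growth_driver("uniform_rotation",
                    delta_edot = kappa_amp * omega0 * sqrt(2),
                    omega = omega0, edot = ed, gamma = omega0 * R / ed)
    },
    "4" = growth_driver("uniform_rotation", delta_edot = dd, omega = omega0,
                        edot = pick(5e-6)),
    "5" = growth_driver("uniform_rotation", delta_edot = dd, omega = omega0,
                        edot = pick(5e-6), L_gz = 5),
    "circle" = , "S3" = growth_driver("uniform_rotation", delta_edot = dd,
                                      omega = omega0, edot = pick(0)),
    "epitrochoid" = , "S7" = growth_driver(
      "two_zone", zone_frac = c(0.5, 0.5),
      zone_omega = c(omega0, 6 * omega0),
      zone_delta_edot = c(dd, 5 * dd), edot = pick(0)),
    "hypotrochoid" = , "S8" = growth_driver(
      "two_zone", zone_frac = c(0.5, 0.5),
      zone_omega = c(omega0, -6 * omega0),
      zone_delta_edot = c(dd, 5 * dd), edot = pick(0)),
    stop("unknown preset key: ", key)
  )
}
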