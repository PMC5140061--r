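#' Fit the growth-driver kinematics to an apical-tip track
#'
#' The central estimator: from a horizontal tip trajectory it recovers the
#' time course of the principal direction of differential growth
#' `psi_g(t)` (direction of the smoothed tip velocity), its magnitude
#' `delta_edot(t)` (speed scaled by `2R/L^2`, when the organ radius and
#' length are known), the mean rotation rate and rotation period
#' `T_r = 2 pi / <dpsi_g/dt>`, and the alternate-maxima period `T_o` of
#' the rate series.
#'
#' One rotation period is discarded at each end of the series before
#' computing summary rates (transients and filter edge effects); the
#' provisional period used for trimming is estimated from the full series
#' first.
#'
#' @param track an [apical_track()] (or data frame with `t`, `x`, `y`).
#' @param R organ radius (mm); optional, needed for a quantitative
#'   `delta_edot`.
#' @param L organ length (mm); optional, as `R`.
#' @param window Savitzky-Golay window (odd samples), `NULL` for automatic
#'   selection from the track's dominant period.
#' @param order Savitzky-Golay polynomial order.
#' @param convention see [estimate_psi_g_from_track()].
#' @param trim_periods rotation periods discarded at each series end for
#'   the summary statistics.
#' @return an object of class `nutation_fit` with components `t`, `psi_g`,
#'   `rate`, `delta_edot`, `mean_rate`, `T_r`, `T_o`, `window`, `R`, `L`.
#' @examples
#' trk <- generate_track("circle", duration = 4 * 13800, dt = 69,
#'                       rho0 = 1, omega = 2 * pi / 13800)
#' fit <- fit_nutation(trk, R = 0.5, L = 10)
#' coef(fit)
#' @export
fit_nutation <- function(track, R = NULL, L = NULL, window = NULL,
                         order = 3, convention = "velocity",
                         trim_periods = 1) {
  if (!inherits(track, "apical_track")) {
    track <- apical_track(track$t, track$x, track$y)
  }
  spec <- smoothing_spec(window, order)
  w <- resolve_window(spec, track)
  psi <- estimate_psi_g_from_track(track, spec, convention)
  dt <- check_uniform_sampling(track$t)

  # rate series: SG derivative of the unwrapped direction (observed run)
  rate <- rep(NA_real_, length(psi))
  ok <- which(!is.na(psi))
  if (length(ok) >= 2 * w) {
    rr <- sg_deriv(psi[ok], dt, w, spec$order)
    rr[c(seq_len(w), (length(rr) - w + 1):length(rr))] <- NA
    rate[ok] <- rr
  }
  delta <- estimate_delta_edot_from_track(track, R, L, spec)

  # provisional period from the raw endpoints, used only to discard the
  # transient; the summary rate is then measured over an exact whole
  # number of rotations (interpolated phase crossing), so the periodic
  # part of psi_g(t) contributes no endpoint bias
  prov <- rotation_period(psi, track$t)
  keep <- rep(TRUE, length(psi))
  if (trim_periods > 0 && is.finite(prov$T_r)) {
    Tp <- abs(prov$T_r) * trim_periods
    keep <- track$t >= (track$t[1] + Tp) &
      track$t <= (track$t[length(track$t)] - Tp)
    if (sum(keep & !is.na(psi)) < 2) keep <- rep(TRUE, length(psi))
  }
  summ <- mean_rate_whole_turns(ifelse(keep, psi, NA), track$t)
  if (is.null(summ)) summ <- rotation_period(ifelse(keep, psi, NA), track$t)
  T_o <- tryCatch(
    maxima_spacing(ifelse(keep, rate, NA), track$t),
    error = function(e) NA_real_)

  structure(list(track = track, t = track$t, psi_g = psi, rate = rate,
                 delta_edot = delta, mean_rate = summ$mean_rate,
                 T_r = summ$T_r, T_o = T_o, window = w, order = spec$order,
                 R = R, L = L, convention = convention,
                 trim_periods = trim_periods),
            class = "nutation_fit")
}

# Mean rotation rate over the largest whole number of 2*pi turns inside
# the observed span, with the end time interpolated at the exact phase
# crossing. Returns NULL when less than one full turn is observed.
mean_rate_whole_turns <- function(psi, times) {
  ok <- !is.na(psi)
  if (sum(ok) < 2) return(NULL)
  p <- psi[ok]; tt <- times[ok]
  sgn <- sign(p[length(p)] - p[1])
  if (sgn == 0) return(NULL)
  q <- sgn * p  # increasing phase
  nturn <- floor((q[length(q)] - q[1]) / (2 * pi))
  if (nturn < 1) return(NULL)
  target <- q[1] + 2 * pi * nturn
  j <- which(q >= target)[1]
  if (is.na(j) || j < 2) return(NULL)
  tc <- tt[j - 1] + (target - q[j - 1]) / (q[j] - q[j - 1]) *
    (tt[j] - tt[j - 1])
  mean_rate <- sgn * 2 * pi * nturn / (tc - tt[1])
  list(mean_rate = mean_rate, T_r = 2 * pi / mean_rate)
}

#' @export
print.nutation_fit <- function(x, ...) {
  cat("Nutation growth-driver fit\n")
  cat(sprintf("  samples: %d (SG window %d, order %d)\n",
              length(x$t), x$window, x$order))
  cat(sprintf("  mean d(psi_g)/dt: %.4g rad/s\n", x$mean_rate))
  cat(sprintf("  rotation period T_r: %.4g s (%.1f min)\n",
              x$T_r, x$T_r / 60))
  if (is.finite(x$T_o)) {
    cat(sprintf("  alternate-maxima period T_o: %.4g s (%.1f min)\n",
                x$T_o, x$T_o / 60))
  } else {
    cat("  alternate-maxima period T_o: not detected\n")
  }
  if (isTRUE(attr(x$delta_edot, "qualitative"))) {
    cat("  delta_edot: qualitative (organ R, L unknown; prefactor 1)\n")
  } else {
    cat(sprintf("  mean delta_edot: %.4g 1/s\n",
                mean(x$delta_edot, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.nutation_fit <- function(object, ...) {
  out <- list(
    n = length(object$t),
    window = object$window,
    mean_rate = object$mean_rate,
    T_r = object$T_r,
    T_o = object$T_o,
    rate_range = range(object$rate, na.rm = TRUE),
    delta_mean = mean(object$delta_edot, na.rm = TRUE),
    delta_cv = stats::sd(object$delta_edot, na.rm = TRUE) /
      mean(object$delta_edot, na.rm = TRUE),
    qualitative = isTRUE(attr(object$delta_edot, "qualitative"))
  )
  class(out) <- "summary.nutation_fit"
  out
}

#' @export
print.summary.nutation_fit <- function(x, ...) {
  cat("Nutation fit summary\n")
  cat(sprintf("  n = %d, SG window = %d\n", x$n, x$window))
  cat(sprintf("  <dpsi_g/dt> = %.4g rad/s;  T_r = %.1f min;  T_o = %s\n",
              x$mean_rate, x$T_r / 60,
              if (is.finite(x$T_o)) sprintf("%.1f min", x$T_o / 60) else "nd"))
  cat(sprintf("  rate range: [%.3g, %.3g] rad/s\n",
              x$rate_range[1], x$rate_range[2]))
  cat(sprintf("  delta_edot: mean %.3g%s, cv %.2f\n", x$delta_mean,
              if (x$qualitative) " (qualitative)" else " 1/s", x$delta_cv))
  invisible(x)
}

#' @export
coef.nutation_fit <- function(object, ...) {
  c(mean_rate = object$mean_rate, T_r = object$T_r, T_o = object$T_o)
}

#' Phase-plot view of a nutation fit
#'
#' Four panels: the tip track; `psi_g(t)`; the rate `dpsi_g/dt` against
#' `psi_g` (mod 2 pi); and `delta_edot` against `psi_g`. The two phase
#' panels distinguish the ellipse mechanisms: rate minima at
#' `psi_g = +/- pi/2` indicate rate modulation, `delta_edot` maxima there
#' indicate amplitude modulation.
#'
#' @param x a `nutation_fit`.
#' @param ... passed to the track panel.
#' @export
plot.nutation_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  plot(x$track, main = "apical track", ...)
  graphics::plot(x$t / 3600, x$psi_g, type = "l", xlab = "t (h)",
                 ylab = expression(psi[g] ~ "(rad)"), main = "direction")
  phase <- wrap_angle(x$psi_g)
  graphics::plot(phase, x$rate, pch = 16, cex = 0.4,
                 xlab = expression(psi[g] ~ "(rad, wrapped)"),
                 ylab = "rate (rad/s)", main = "rate vs direction")
  graphics::plot(phase, x$delta_edot, pch = 16, cex = 0.4,
                 xlab = expression(psi[g] ~ "(rad, wrapped)"),
                 ylab = expression(Delta %.% dot(E)),
                 main = "drive vs direction")
  invisible(x)
}
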