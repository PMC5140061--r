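#' Horizontal apical-tip track
#'
#' Time series of the tip's horizontal projection with derived polar view:
#' `rho = sqrt(x^2 + y^2)`, `theta = atan2(y, x)` unwrapped over time.
#'
#' @param times times (s), strictly increasing.
#' @param x,y horizontal tip coordinates (mm).
#' @return a data frame of class `apical_track` with columns
#'   `t, x, y, rho, theta`.
#' @export
apical_track <- function(times, x, y) {
  stopifnot(length(times) == length(x), length(x) == length(y))
  if (any(diff(times) <= 0)) stop("track times must be strictly increasing")
  out <- data.frame(t = times, x = x, y = y,
                    rho = sqrt(x ^ 2 + y ^ 2),
                    theta = unwrap_angle(atan2(y, x)))
  class(out) <- c("apical_track", "data.frame")
  out
}

#' @export
print.apical_track <- function(x, ...) {
  cat("<apical_track> ", nrow(x), "samples over",
      format(diff(range(x$t))), "s; median rho",
      format(stats::median(x$rho), digits = 4), "mm\n")
  invisible(x)
}

#' @export
plot.apical_track <- function(x, ..., asp = 1, type = "l",
                              xlab = "x (mm)", ylab = "y (mm)") {
  graphics::plot(x$x, x$y, asp = asp, type = type,
                 xlab = xlab, ylab = ylab, ...)
  graphics::points(0, 0, pch = 3)
  invisible(x)
}

#' Generate synthetic apical-tip tracks
#'
#' Analytic parametric curves of the pattern classes seen in nutation
#' recordings, sampled uniformly and optionally degraded with Gaussian
#' position noise. Trochoids are built as the sum of two rotating vectors
#' with angular rates `omega1` and `omega2` (same sign: epitrochoid-like
#' loops; opposite sign: hypotrochoid-like).
#'
#' @param pattern one of `"circle"`, `"ellipse"`, `"epitrochoid"`,
#'   `"hypotrochoid"`, `"line"`.
#' @param duration total duration (s); should cover at least 3 slow
#'   periods.
#' @param dt sampling interval (s).
#' @param rho0 radius of the circle / first rotating vector (mm).
#' @param omega angular rate of the circle, ellipse or first rotating
#'   vector (rad/s).
#' @param ab semi-axes `c(a, b)` of the ellipse (mm).
#' @param rho2,omega_ratio second rotating vector: radius (mm) and rate as
#'   a multiple of `omega` (sign included; defaults +6 / -6 for the epi-
#'   and hypotrochoid presets).
#' @param phase0 initial phase (rad).
#' @param noise_sd Gaussian position noise, as a fraction of the pattern
#'   scale (median radius).
#' @param seed RNG seed for the noise (restores the RNG state on exit).
#' @return an [apical_track()].
#' @examples
#' trk <- generate_track("circle", duration = 3 * 13800, dt = 60,
#'                       rho0 = 1, omega = 2 * pi / 13800)
#' @export
generate_track <- function(pattern = c("circle", "ellipse", "epitrochoid",
                                       "hypotrochoid", "line"),
                           duration, dt, rho0 = 1, omega,
                           ab = c(1.5, 0.75), rho2 = rho0 / 3,
                           omega_ratio = if (pattern == "hypotrochoid") -6 else 6,
                           phase0 = 0, noise_sd = 0, seed = NULL) {
  pattern <- match.arg(pattern)
  stopifnot(duration > 0, dt > 0)
  tt <- seq(0, duration, by = dt)
  ph <- phase0 + omega * tt
  xy <- switch(pattern,
    circle = cbind(rho0 * cos(ph), rho0 * sin(ph)),
    ellipse = cbind(ab[1] * cos(ph), ab[2] * sin(ph)),
    epitrochoid = ,
    hypotrochoid = {
      ph2 <- phase0 + omega_ratio * omega * tt
      cbind(rho0 * cos(ph) + rho2 * cos(ph2),
            rho0 * sin(ph) + rho2 * sin(ph2))
    },
    line = cbind(rho0 * cos(ph) * cos(phase0),
                 rho0 * cos(ph) * sin(phase0))
  )
  if (noise_sd > 0) {
    scale <- stats::median(sqrt(rowSums(xy ^ 2)))
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    xy <- xy + matrix(stats::rnorm(2 * length(tt), sd = noise_sd * scale),
                      ncol = 2)
  }
  apical_track(tt, xy[, 1], xy[, 2])
}
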