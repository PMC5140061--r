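#' Smoothing and differentiation settings for track inversion
#'
#' Savitzky-Golay local-polynomial smoothing is used for all derivatives of
#' tracked coordinates. The window must be odd and larger than the
#' polynomial order. When `window` is `NULL` it is chosen per track as one
#' tenth of the dominant period estimated by autocorrelation.
#'
#' @param window filter window length (samples, odd), or `NULL` for
#'   automatic selection.
#' @param order polynomial order.
#' @return an object of class `smoothing_spec`.
#' @export
smoothing_spec <- function(window = NULL, order = 3) {
  if (!is.null(window)) {
    window <- as.integer(window)
    if (window %% 2L == 0L || window <= order) {
      stop("window must be odd and greater than the polynomial order")
    }
  }
  structure(list(window = window, order = as.integer(order)),
            class = "smoothing_spec")
}

# Dominant period of a zero-mean-ish oscillatory series, in samples: lag of
# the first local maximum of the autocorrelation after its first
# sign change. Falls back to n/3 when no oscillation is detected.
dominant_period_samples <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  ac <- stats::acf(x, lag.max = n - 2, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  neg <- which(ac < 0)
  if (length(neg) > 0) {
    rest <- ac[neg[1]:length(ac)]
    im <- local_maxima(rest)
    im <- im[rest[im] > 0.1]
    if (length(im) > 0) return(neg[1] + im[1] - 2)
  }
  max(6L, floor(n / 3))
}

# Resolve a smoothing_spec against a concrete track: pick the window.
resolve_window <- function(spec, track) {
  n <- nrow(track)
  w <- spec$window
  if (is.null(w)) {
    per <- dominant_period_samples(track$x)
    w <- round(per / 10)
  }
  w <- max(w, spec$order + 2)
  w <- min(w, floor((n - 1) / 2))
  if (w %% 2 == 0) w <- w + 1
  as.integer(w)
}

# Savitzky-Golay derivative of order m on a uniformly sampled series.
sg_deriv <- function(x, dt, window, order, m = 1) {
  signal::sgolayfilt(x, p = order, n = window, m = m, ts = dt)
}

check_uniform_sampling <- function(times) {
  dts <- diff(times)
  if (diff(range(dts)) > 1e-6 * stats::median(dts)) {
    stop("track must be uniformly sampled for Savitzky-Golay differentiation")
  }
  stats::median(dts)
}

#' Estimate the principal direction of differential growth from a track
#'
#' The model slaves the curvature direction to the growth direction, making
#' the direction of the smoothed tip velocity a direct estimate of
#' `psi_g(t)`: `psi_g = atan2(dy/dt, dx/dt)`, full quadrant, unwrapped over
#' time. Samples where the tip speed falls below 1% of the median speed are
#' masked (the direction is meaningless at a stationary tip), as is one
#' filter window at each end.
#'
#' @param track an [apical_track()], uniformly sampled.
#' @param spec a [smoothing_spec()].
#' @param convention `"velocity"` (full-quadrant direction of the tip
#'   velocity; default) or `"printed"` (the y-axis-referenced
#'   `atan(dx/dy)` variant; differs by a constant offset that cancels in
#'   all rates and periods).
#' @return numeric vector of unwrapped `psi_g` estimates (rad), `NA` where
#'   masked, aligned with `track$t`.
#' @export
estimate_psi_g_from_track <- function(track, spec = smoothing_spec(),
                                      convention = c("velocity", "printed")) {
  convention <- match.arg(convention)
  dt <- check_uniform_sampling(track$t)
  w <- resolve_window(spec, track)
  if (nrow(track) < 2 * w) stop("track too short for the smoothing window")
  span <- max(diff(range(track$x)), diff(range(track$y)))
  if (span <= 1e-12 * max(abs(track$x), abs(track$y), 1)) {
    stop("no signal: the tip is stationary")
  }
  vx <- sg_deriv(track$x, dt, w, spec$order)
  vy <- sg_deriv(track$y, dt, w, spec$order)
  speed <- sqrt(vx ^ 2 + vy ^ 2)
  floor_speed <- 0.01 * stats::median(speed)
  psi <- if (convention == "velocity") atan2(vy, vx) else atan(vx / vy)
  psi[speed < floor_speed] <- NA
  n <- length(psi)
  psi[c(seq_len(w), (n - w + 1):n)] <- NA
  unwrap_angle(psi)
}

#' Estimate the differential-growth magnitude from a track
#'
#' Under the whole-organ hypotheses (uniform curvature in a single plane,
#' small curvature `C = 2 rho / L^2`), the tip speed is proportional to the
#' differential-growth drive: `delta_edot = (2 R / L^2) * sqrt(vx^2 +
#' vy^2)`. Without `R` and `L` the estimate is returned up to that
#' prefactor (prefactor 1) and is only qualitatively comparable.
#'
#' @param track an [apical_track()].
#' @param R organ radius (mm), or `NULL`.
#' @param L organ length (mm), or `NULL`.
#' @param spec a [smoothing_spec()].
#' @return numeric vector (1/s), nonnegative, `NA` in one window at each
#'   end; attribute `qualitative` is `TRUE` when the prefactor is unknown.
#' @export
estimate_delta_edot_from_track <- function(track, R = NULL, L = NULL,
                                           spec = smoothing_spec()) {
  dt <- check_uniform_sampling(track$t)
  w <- resolve_window(spec, track)
  vx <- sg_deriv(track$x, dt, w, spec$order)
  vy <- sg_deriv(track$y, dt, w, spec$order)
  qual <- is.null(R) || is.null(L)
  pref <- if (qual) 1 else {
    stopifnot(R > 0, L > 0)
    2 * R / L ^ 2
  }
  out <- pref * sqrt(vx ^ 2 + vy ^ 2)
  n <- length(out)
  out[c(seq_len(w), (n - w + 1):n)] <- NA
  attr(out, "qualitative") <- qual
  out
}

#' Mean rotation rate and rotation period of the growth direction
#'
#' The mean rate is the total unwrapped change of `psi_g` divided by the
#' elapsed time over the observed (non-masked) span; the rotation period is
#' `T_r = 2 pi / mean rate` (signed by the rotation sense).
#'
#' @param psi_g unwrapped direction series (rad), `NA` allowed.
#' @param times times (s) aligned with `psi_g`.
#' @return list with `mean_rate` (rad/s) and `T_r` (s).
#' @examples
#' rotation_period(4.6e-4 * (0:100), 0:100)  # T_r ~ 230 min
#' @export
rotation_period <- function(psi_g, times) {
  ok <- !is.na(psi_g)
  if (sum(ok) < 2) stop("need at least two observed samples")
  p <- psi_g[ok]; tt <- times[ok]
  mean_rate <- (p[length(p)] - p[1]) / (tt[length(tt)] - tt[1])
  if (mean_rate == 0) stop("no rotation signal: mean rate is zero")
  list(mean_rate = mean_rate, T_r = 2 * pi / mean_rate)
}

#' Period from the spacing of alternate rate maxima
#'
#' Consecutive maxima of `dpsi_g/dt` are expected half a rotation apart, so
#' the average time between every other maximum spans a full rotation and
#' estimates the rotation period independently of the mean rate.
#'
#' @param rate rate series `dpsi_g/dt` (rad/s), `NA` allowed.
#' @param times times (s).
#' @param smooth_window optional odd window for light Savitzky-Golay
#'   smoothing before peak detection (`NULL` = none).
#' @return `T_o` (s), the mean alternate-maxima spacing.
#' @export
maxima_spacing <- function(rate, times, smooth_window = NULL) {
  ok <- !is.na(rate)
  r <- rate[ok]; tt <- times[ok]
  if (!is.null(smooth_window)) {
    r <- signal::sgolayfilt(r, p = 2, n = smooth_window)
  }
  if (diff(range(r)) <= 1e-3 * max(abs(r), 1e-300)) {
    stop("undetectable: rate series is flat")
  }
  im <- local_maxima(r)
  # keep only prominent maxima (upper half of the observed variation)
  im <- im[r[im] >= min(r) + 0.5 * diff(range(r))]
  if (length(im) < 3) {
    stop("undetectable: fewer than 3 rate maxima found")
  }
  tm <- tt[im]
  mean(tm[seq_along(tm)[-(1:2)]] - tm[seq_len(length(tm) - 2)])
}

# Central-difference gradient with one-sided ends (uniform or not).
num_gradient <- function(y, t) {
  n <- length(y)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (t[2] - t[1])
  g[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  }
  g
}

#' Invert the growth driver from 3D curvature fields
#'
#' Exact inverse of the curvature evolution laws: per material segment,
#' `psi_g - psi_c = atan2(C R dpsi_c/dt, d(CR)/dt)` and
#' `delta_edot = sqrt((d(CR)/dt)^2 + (C R dpsi_c/dt)^2)`. Time derivatives
#' are material (the rows of `fields` must follow the same material segment
#' across time, as produced by [organ_fields()]), computed by central
#' differences. Samples where both rate components vanish are masked.
#'
#' @param fields data frame with columns `t`, `segment`, `C`, `psi_c`
#'   (Lagrangian sampling: `segment` identifies the material element).
#' @param R organ radius (mm).
#' @return data frame `t, segment, psi_g, delta_edot` (`psi_g` unwrapped
#'   per segment; masked samples `NA`).
#' @export
invert_from_3d <- function(fields, R) {
  stopifnot(all(c("t", "segment", "C", "psi_c") %in% names(fields)))
  res <- lapply(split(fields, fields$segment), function(df) {
    df <- df[order(df$t), ]
    k <- df$C * R
    psi <- unwrap_angle(df$psi_c)
    dk <- num_gradient(k, df$t)
    dpsi <- num_gradient(psi, df$t)
    a <- k * dpsi
    delta <- sqrt(dk ^ 2 + a ^ 2)
    tol <- 1e-14 + 1e-10 * max(delta)
    dead <- delta < tol
    psi_g <- psi + atan2(a, dk)
    psi_g[dead] <- NA
    delta[dead] <- NA
    data.frame(t = df$t, segment = df$segment,
               psi_g = unwrap_angle(psi_g), delta_edot = delta)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Whole-organ curvature from the tip projection
#'
#' Under the whole-organ hypotheses (uniform curvature in a single plane,
#' length `L` fixed), the polar tip coordinates map to the posture:
#' `psi_c = theta`, and `rho = (1 - cos(C L)) / C`, solved numerically for
#' `C`. The relation is monotone (hence uniquely invertible) for
#' `C * L` up to `u* = 2.3311...` (the root of `u = tan(u/2)`), where the
#' organ arcs over and the tip starts folding back toward the base; larger
#' `rho` raises a posture-out-of-range error. In `small_curvature` mode
#' the first-order relation `C = 2 rho / L^2` is used instead.
#'
#' @param rho,theta polar tip coordinates (mm, rad); vectors.
#' @param L organ length (mm).
#' @param mode `"exact"` (numeric arc inversion) or `"small_curvature"`.
#' @return data frame with columns `C` (1/mm) and `psi_c` (rad; `NA` where
#'   `rho = 0`).
#' @export
curvature_from_tip <- function(rho, theta, L, mode = c("exact",
                                                       "small_curvature")) {
  mode <- match.arg(mode)
  stopifnot(L > 0, all(rho >= 0))
  u_star <- 2.331122370414423  # root of u = tan(u/2): fold-over arc angle
  rho_max <- L * (1 - cos(u_star)) / u_star
  if (any(rho > rho_max)) {
    stop("posture out of range: rho exceeds the invertible (pre-fold-over) branch")
  }
  C <- if (mode == "small_curvature") {
    2 * rho / L ^ 2
  } else {
    vapply(rho, function(r) {
      if (r == 0) return(0)
      f <- function(C) (1 - cos(C * L)) / C - r
      stats::uniroot(f, c(1e-12, u_star / L), tol = 1e-12,
                     extendInt = "no")$root
    }, numeric(1))
  }
  data.frame(C = C, psi_c = ifelse(rho > 0, theta, NA))
}
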