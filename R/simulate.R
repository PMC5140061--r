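#' Simulation configuration
#'
#' Bundles driver, organ geometry, integration settings and the noise model
#' into a validated config. Guard: `dt` times the fastest driver rate must
#' stay below 1e-2 so explicit stepping is comfortably stable.
#'
#' @param driver a [growth_driver()], or `preset` key.
#' @param preset preset key passed to [preset_driver()] when `driver` is
#'   missing.
#' @param R organ radius (mm).
#' @param L0 initial organ length (mm).
#' @param n_segments number of material segments.
#' @param C0 initial curvature (1/mm): a scalar/vector, or `"centered"` to
#'   start on the centered periodic orbit of the driver (computed by
#'   integrating the curvature-vector rate over one driver period).
#' @param psi_c0 initial curvature direction (rad), ignored for
#'   `"centered"`.
#' @param dt time step (s); default `driver period / 1000`.
#' @param t_end simulation horizon (s); default 5 driver periods.
#' @param save_stride save every `save_stride`-th step.
#' @param noise_sd tip position noise as a fraction of the track's median
#'   radius (applied to the track only, not the dynamics).
#' @param seed RNG seed for the noise.
#' @param method integration scheme, `"euler"` or `"midpoint"`.
#' @param keep_quadratic see [step_segment()].
#' @return an object of class `run_config`.
#' @export
run_config <- function(driver = NULL, preset = NULL, R = 0.5, L0 = 10,
                       n_segments = 100, C0 = "centered", psi_c0 = 0,
                       dt = NULL, t_end = NULL, save_stride = 5,
                       noise_sd = 0, seed = NULL,
                       method = c("euler", "midpoint"),
                       keep_quadratic = FALSE) {
  method <- match.arg(method)
  if (is.null(driver)) {
    if (is.null(preset)) stop("provide a driver or a preset key")
    driver <- preset_driver(preset, R = R)
  }
  per <- driver_period(driver)
  # horizon for a non-rotating driver: the time for the drive to build the
  # curvature vector up to |kappa| = 0.6 (safely inside C*R < 1)
  char_time <- if (is.finite(per)) per else {
    dd <- max(driver$delta_edot, driver$zone_delta_edot, 0)
    if (dd > 0) 0.6 / dd else if (driver$edot > 0) 1 / driver$edot else 1
  }
  if (is.null(t_end)) t_end <- if (is.finite(per)) 5 * per else char_time
  if (is.null(dt)) {
    dt <- min(char_time / 1000, 8e-3 / max_rate(driver))
  }
  if (dt * max_rate(driver) >= 1e-2) {
    stop("unstable configuration: dt * max driver rate must be < 1e-2")
  }
  structure(list(driver = driver, preset = preset, R = R, L0 = L0,
                 n_segments = n_segments, C0 = C0, psi_c0 = psi_c0,
                 dt = dt, t_end = t_end, save_stride = save_stride,
                 noise_sd = noise_sd, seed = seed, method = method,
                 keep_quadratic = keep_quadratic),
            class = "run_config")
}

# Fastest rate scale of a driver (rad/s or 1/s), for the stability guard.
max_rate <- function(driver) {
  rates <- c(driver$edot, driver$gamma * driver$edot / 1,
             driver$delta_edot, driver$zone_delta_edot,
             if (!is.null(driver$omega)) abs(driver$omega) *
               (1 + abs(driver$a %||% 0)),
             if (!is.null(driver$zone_omega)) abs(driver$zone_omega))
  max(c(rates, 1e-12), na.rm = TRUE)
}

#' Initial curvature vector on the centered periodic orbit
#'
#' For a rotating driver the curvature vector follows
#' `kappa(t) = kappa(0) + integral of the drive`; the orbit is a closed
#' curve whose center is set by the initial condition. This helper
#' integrates the drive over one driver period (from a zero start, same
#' explicit step as the simulation) and returns the initial `kappa` that
#' centers the orbit on the origin, i.e. centers the apical pattern on the
#' organ base.
#'
#' @param driver a [growth_driver()] (s-independent rules).
#' @param R organ radius (mm), needed for the proprioceptive damping rate.
#' @param dt integration step (s).
#' @return numeric `c(kx, ky)`.
#' @export
centered_initial_kappa <- function(driver, R = 0.5,
                                   dt = driver_period(driver) / 1000) {
  per <- driver_period(driver)
  if (!is.finite(per)) stop("centered start needs a periodic driver")
  nstep <- ceiling(per / dt)
  kap <- matrix(0, 1, 2)
  acc <- c(0, 0)
  t <- 0
  d <- driver
  for (i in seq_len(nstep)) {
    dv <- evaluate_driver(d, 0, t, L = 1)
    kap <- kap + dt * kappa_rate(kap, dv$edot, dv$delta_edot, dv$psi_g,
                                 d$gamma, R)
    acc <- acc + kap[1, ]
    d <- advance_driver(d, dt)
    t <- t + dt
  }
  -acc / nstep
}

#' Run a nutation simulation
#'
#' Evolves the discrete organ under the configured driver, saving organ
#' states at the configured stride and assembling the horizontal apical-tip
#' track (optionally noised). Deterministic for a given config and seed.
#'
#' @param config a [run_config()]; alternatively pass arguments for
#'   `run_config()` via `...`.
#' @param ... forwarded to [run_config()] when `config` is missing.
#' @return an object of class `nutation_sim`: list with `config`, `states`
#'   (saved [organ_state()]s), `track` (an [apical_track()]), `psi_g`
#'   (driver direction at the apex for each saved state) and `max_kappa`
#'   diagnostics.
#' @examples
#' \donttest{
#' sim <- simulate_organ(preset = "circle", t_end = 2 * 13800)
#' plot(sim$track)
#' }
#' @export
simulate_organ <- function(config = NULL, ...) {
  if (is.null(config)) config <- run_config(...)
  stopifnot(inherits(config, "run_config"))
  driver <- config$driver
  two_zone <- driver$rule == "two_zone"

  if (identical(config$C0, "centered") &&
      !is.finite(driver_period(driver))) {
    config$C0 <- 0  # non-rotating driver: start straight
  }
  if (identical(config$C0, "centered")) {
    if (two_zone) {
      # each zone is a uniform rotation: centered start per zone, analytic
      k0 <- cbind(0, -driver$zone_delta_edot / driver$zone_omega)
      frac_base <- driver$zone_frac[1]
      nbase <- round(config$n_segments * frac_base)
      kap0 <- rbind(
        matrix(k0[1, ], nbase, 2, byrow = TRUE),
        matrix(k0[2, ], config$n_segments - nbase, 2, byrow = TRUE))
    } else {
      k0 <- centered_initial_kappa(driver, config$R, config$dt)
      kap0 <- matrix(k0, config$n_segments, 2, byrow = TRUE)
    }
    organ <- organ_state(config$R, config$L0 / config$n_segments,
                         C = 0, psi_c = 0, n_segments = config$n_segments)
    organ$kappa <- kap0
    km <- sqrt(rowSums(kap0 ^ 2))
    organ$psi_memory <- ifelse(km > 0, atan2(kap0[, 2], kap0[, 1]), 0)
  } else {
    organ <- organ_state(config$R, config$L0 / config$n_segments,
                         C = config$C0, psi_c = config$psi_c0,
                         n_segments = config$n_segments)
  }

  nstep <- ceiling(config$t_end / config$dt)
  nsaves <- length(seq(0, nstep, by = config$save_stride))
  states <- vector("list", nsaves)
  psi_g_log <- numeric(nsaves)
  max_kappa <- numeric(nsaves)
  isave <- 1L
  states[[1]] <- organ
  psi_g_log[1] <- evaluate_driver(driver, organ_length(organ), 0,
                                  L = organ_length(organ))$psi_g[1]
  max_kappa[1] <- sqrt(max(rowSums(organ$kappa ^ 2)))

  for (i in seq_len(nstep)) {
    organ <- advance_organ(organ, driver, config$dt, method = config$method,
                           keep_quadratic = config$keep_quadratic)
    driver <- advance_driver(driver, config$dt)
    if (i %% config$save_stride == 0) {
      isave <- isave + 1L
      states[[isave]] <- organ
      L <- organ_length(organ)
      psi_g_log[isave] <- evaluate_driver(driver, L, organ$time,
                                          L = L)$psi_g[1]
      max_kappa[isave] <- sqrt(max(rowSums(organ$kappa ^ 2)))
    }
  }
  states <- states[seq_len(isave)]
  track <- track_tip(states)
  if (config$noise_sd > 0) {
    scale <- stats::median(track$rho)
    if (!is.null(config$seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(config$seed)
    }
    track <- apical_track(
      track$t,
      track$x + stats::rnorm(nrow(track), sd = config$noise_sd * scale),
      track$y + stats::rnorm(nrow(track), sd = config$noise_sd * scale))
  }
  structure(list(config = config, states = states, track = track,
                 psi_g = psi_g_log[seq_len(isave)],
                 max_kappa = max_kappa[seq_len(isave)]),
            class = "nutation_sim")
}

#' @export
print.nutation_sim <- function(x, ...) {
  cat("<nutation_sim> ", x$config$driver$rule, "driver,",
      length(x$states), "saved states\n")
  cat("  t:", format(x$states[[1]]$time), "to",
      format(x$states[[length(x$states)]]$time), "s;  max C*R:",
      format(max(x$max_kappa), digits = 4), "\n")
  invisible(x)
}

#' @export
plot.nutation_sim <- function(x, ...) {
  plot(x$track, ...)
  invisible(x)
}

#' Long-format curvature fields of a simulation
#'
#' One row per material segment per saved state; the per-segment rows are
#' Lagrangian (same material element across time), which is what the 3D
#' inversion expects.
#'
#' @param sim a `nutation_sim`.
#' @return data frame with columns `t, segment, s, rest_length, C, psi_c`.
#' @export
organ_fields <- function(sim) {
  do.call(rbind, lapply(sim$states, function(o) {
    df <- as.data.frame(o)
    data.frame(t = o$time, segment = seq_len(nrow(df)), df)
  }))
}
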