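# Shared fixtures. Simulations are deterministic, so they are computed once
# per test run and memoised here; every test reads the same objects.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, config_fn) {
  if (!exists(key, .sim_cache)) {
    assign(key, simulate_organ(config_fn()), .sim_cache)
  }
  get(key, .sim_cache)
}

omega0 <- 2 * pi / 13800  # base angular frequency, rad/s (230 min period)

sim_circle <- function() cached_sim("circle", function() {
  run_config(preset = "circle")
})
sim_circle_noise <- function() cached_sim("circle_noise", function() {
  run_config(preset = "circle", noise_sd = 0.01, seed = 101)
})
sim_rate_mod <- function() cached_sim("rate_mod", function() {
  run_config(preset = "0")
})
sim_amp_mod <- function() cached_sim("amp_mod", function() {
  run_config(preset = "1")
})
sim_epi <- function() cached_sim("epi", function() {
  run_config(preset = "epitrochoid")
})
sim_hypo <- function() cached_sim("hypo", function() {
  run_config(preset = "hypotrochoid")
})
sim_growth <- function() cached_sim("growth", function() {
  run_config(preset = "4")
})
sim_subapical <- function() cached_sim("subapical", function() {
  run_config(preset = "5")
})
sim_proprio <- function(which = 1) {
  key <- paste0("proprio", which)
  ics <- list(list(C0 = 0.002, psi_c0 = 0), list(C0 = 0.02, psi_c0 = 2))
  cached_sim(key, function() {
    do.call(run_config, c(list(preset = "3"), ics[[which]]))
  })
}

# Least-squares (Kasa) circle fit in the plane; returns center and radii of
# the points about it.
fit_circle_radii <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x ^ 2 + y ^ 2
  sol <- qr.solve(A, b)
  sqrt((x - sol[1]) ^ 2 + (y - sol[2]) ^ 2)
}

# Radial deviation of the last full period of a track, relative to its
# mean radius.
last_period_radial_dev <- function(track, period) {
  last <- track[track$t >= max(track$t) - period, ]
  (max(last$rho) - min(last$rho)) / mean(last$rho)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
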