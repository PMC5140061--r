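test_that("a segment without differential growth only elongates", {
  seg <- list(rest_length = 1, C = 0.3, psi_c = 0.8)
  out <- step_segment(seg, R = 1, edot = 0.05, delta_edot = 0, psi_g = 2,
                      gamma = 0, dt = 0.1)
  expect_equal(out$C, 0.3)
  expect_equal(out$psi_c, 0.8)
  expect_equal(out$rest_length, 1 * (1 + 0.05 * 0.1))
})

test_that("an aligned driver grows C*R linearly; with the quadratic factor it saturates as tanh", {
  # linear regime
  seg <- list(rest_length = 1, C = 0.1, psi_c = 0)
  out <- step_segment(seg, R = 1, edot = 0, delta_edot = 0.2, psi_g = 0,
                      dt = 0.05)
  expect_equal(out$C, 0.1 + 0.2 * 0.05, tolerance = 1e-15)
  expect_equal(out$psi_c, 0)

  # fine-step reference integration of the saturating law from C = 0:
  # C*R(t) = tanh(delta_edot * t)
  seg <- list(rest_length = 1, C = 0, psi_c = 0)
  dt <- 1e-4
  for (i in seq_len(20000)) {
    seg <- step_segment(seg, R = 0.5, edot = 0, delta_edot = 1, psi_g = 0,
                        dt = dt, keep_quadratic = TRUE)
  }
  expect_equal(seg$C * 0.5, tanh(2), tolerance = 1e-4)

  expect_error(step_segment(list(rest_length = 1, C = 0.9, psi_c = 0),
                            R = 1, edot = 0, delta_edot = 10, psi_g = 0,
                            dt = 0.1),
               "geometry error")
})

test_that("stepping the curvature vector is equivalent to the magnitude/direction laws", {
  # for C > 0 the kappa update must match an explicit Euler update of
  # d(CR)/dt = delta_edot*cos(psi_g - psi_c) - gamma*edot*C and
  # dpsi_c/dt = delta_edot*sin(psi_g - psi_c)/(CR)
  set.seed(11)
  for (i in 1:25) {
    R <- runif(1, 0.3, 1.2)
    C <- runif(1, 0.05, 0.6) / R
    psi <- runif(1, -pi, pi)
    dd <- runif(1, 0, 0.3)
    psig <- runif(1, -pi, pi)
    gam <- runif(1, 0, 2)
    ed <- runif(1, 0, 0.1)
    dt <- 1e-4
    out <- step_segment(list(rest_length = 1, C = C, psi_c = psi), R,
                        edot = ed, delta_edot = dd, psi_g = psig,
                        gamma = gam, dt = dt)
    k <- C * R
    k2 <- k + dt * (dd * cos(psig - psi) - gam * ed * k / R)
    psi2 <- psi + dt * dd * sin(psig - psi) / k
    # the two explicit schemes agree up to their O(dt^2) difference
    expect_equal(out$C * R, k2, tolerance = 1e-6)
    expect_lt(abs(wrap_angle(out$psi_c - psi2)), 1e-6)
  }
})

test_that("constant-direction drive aligns the curvature monotonically", {
  drv <- growth_driver("constant", delta_edot = 0.02, psi_g0 = 0)
  org <- organ_state(1, 1, C = 0.01, psi_c = 2.5, n_segments = 1)
  gap <- abs(2.5)
  Cs <- curvature(org)
  for (i in 1:400) {
    org <- advance_organ(org, drv, dt = 0.1)
    gap_new <- abs(wrap_angle(curv_direction(org) - 0))
    expect_lte(gap_new, gap + 1e-12)
    gap <- gap_new
  }
  expect_gt(curvature(org), Cs)
  expect_lt(gap, 0.05)
  # once aligned, the orthogonal projection vanishes identically
  expect_equal(unname(project_growth(1, 0.7, 0.7))[2], 0)
})

test_that("a rotating driver settles on a circular limit cycle of radius delta_edot/omega", {
  om <- 0.5; dd <- 0.1
  drv <- growth_driver("uniform_rotation", delta_edot = dd, omega = om)
  dt <- 2 * pi / om / 4000
  run <- function(C0, psi0) {
    org <- organ_state(1, 1, C = C0, psi_c = psi0, n_segments = 1)
    d <- drv
    kap <- matrix(NA_real_, 8000, 2)
    for (i in 1:8000) {
      org <- advance_organ(org, d, dt)
      d <- advance_driver(d, dt)
      kap[i, ] <- org$kappa
    }
    kap
  }
  for (ic in list(c(0.05, 0), c(0.2, 2))) {
    kap <- run(ic[1], ic[2])
    radii <- fit_circle_radii(kap[, 1], kap[, 2])
    expect_lt(diff(range(radii)) / mean(radii), 5e-3)
    expect_equal(mean(radii), dd / om, tolerance = 1e-2)
    # the period equals the driver period regardless of initial condition:
    # kappa returns to its value one full period (4000 steps) earlier
    expect_lt(max(abs(kap[8000, ] - kap[4000, ])), 1e-3 * dd / om)
  }
})

test_that("proprioception creates a single attracting orbit with the predicted amplitude", {
  om <- 1; lam <- 0.7; dd <- 0.3; R <- 1
  drv <- growth_driver("uniform_rotation", delta_edot = dd, omega = om,
                       edot = lam, gamma = 1)   # gamma*edot/R = lam
  dt <- 2 * pi / om / 2000
  nstep <- ceiling(14 * (1 / lam) / dt)  # 14 damping times
  run <- function(C0, psi0) {
    org <- organ_state(R, 1, C = C0, psi_c = psi0, n_segments = 1)
    d <- drv
    for (i in seq_len(nstep)) {
      org <- advance_organ(org, d, dt)
      d <- advance_driver(d, dt)
    }
    org$kappa
  }
  k1 <- run(0.01, 0)
  k2 <- run(0.29, 2.5)
  expect_lt(max(abs(k1 - k2)), 1e-6)
  expect_equal(sqrt(sum(k1 ^ 2)), dd / sqrt(om ^ 2 + lam ^ 2),
               tolerance = 1e-2)
})

test_that("without drive the state is conserved bit-for-bit while lengths compound", {
  drv <- growth_driver("constant", delta_edot = 0, edot = 0.01)
  org <- organ_state(0.5, 0.2, C = c(0.1, 0, 0.3), psi_c = c(1, 0, -2),
                     n_segments = 3)
  kap0 <- org$kappa
  org2 <- org
  for (i in 1:50) org2 <- advance_organ(org2, drv, dt = 0.1)
  expect_identical(org2$kappa, kap0)
  expect_equal(org2$rest_length, rep(0.2 * (1 + 0.01 * 0.1) ^ 50, 3))
})

test_that("whole-organ dilation rescales abscissas and freezes shape", {
  drv <- growth_driver("uniform_rotation", delta_edot = 0, edot = 0.02,
                       omega = 1)
  org <- organ_state(0.5, 0.1, C = 0.05, psi_c = seq(0, 1, length.out = 50),
                     n_segments = 50)
  out <- advance_organ(org, drv, dt = 0.1)
  expect_equal(abscissa(out), abscissa(org) * (1 + 0.02 * 0.1))
  expect_equal(curvature(out), curvature(org))
  expect_equal(curv_direction(out), curv_direction(org))
})

test_that("segments below the growth zone are frozen", {
  drv <- growth_driver("uniform_rotation", delta_edot = 0.01, edot = 0.005,
                       omega = 0.3, L_gz = 4)
  org0 <- organ_state(0.5, 0.1, C = 0.02, psi_c = 0, n_segments = 100)
  # segments below the zone at t = 0 stay below it (the boundary only
  # rises as the organ elongates), so they must be bit-frozen throughout
  s_mid0 <- abscissa(org0) + org0$rest_length / 2
  frozen0 <- s_mid0 < organ_length(org0) - 4
  org <- org0
  d <- drv
  for (i in 1:200) {
    org <- advance_organ(org, d, dt = 0.05)
    d <- advance_driver(d, dt = 0.05)
  }
  expect_true(any(frozen0) && any(!frozen0))
  expect_equal(curvature(org)[frozen0], rep(0.02, sum(frozen0)))
  expect_equal(curv_direction(org)[frozen0], rep(0, sum(frozen0)))
  expect_equal(org$rest_length[frozen0], rep(0.1, sum(frozen0)))
  # the zone boundary has risen: more segments are frozen now, and those
  # that left the zone mid-run carry a curvature different from the
  # initial one (the stored arrangement)
  s_mid <- abscissa(org) + org$rest_length / 2
  frozen1 <- s_mid < organ_length(org) - 4
  expect_gt(sum(frozen1), sum(frozen0))
  exited <- frozen1 & !frozen0
  expect_true(all(abs(curvature(org)[exited] - 0.02) > 0))
  # growing segments have elongated
  expect_gt(min(org$rest_length[!frozen1]), 0.1)
})

test_that("boundary velocities equal the cumulative elongation quadrature", {
  org <- organ_state(0.5, 0.1, C = 0.02, psi_c = 0.4, n_segments = 100)
  drv <- growth_driver("constant", delta_edot = 0, edot = 0.01, L_gz = 4)
  dt <- 0.01
  out <- advance_organ(org, drv, dt)
  s0 <- c(0, cumsum(org$rest_length))
  s1 <- c(0, cumsum(out$rest_length))
  v_obs <- (s1 - s0) / dt
  s_mid <- abscissa(org) + org$rest_length / 2
  edot_eff <- ifelse(s_mid >= organ_length(org) - 4, 0.01, 0)
  v_expect <- growth_velocity(org, edot_eff)
  expect_lt(max(abs(v_obs - v_expect)), 0.01 * 0.1)  # within one segment
})

test_that("the midpoint scheme converges at second order on a rotating driver", {
  om <- 0.8; dd <- 0.2
  drv <- growth_driver("uniform_rotation", delta_edot = dd, omega = om)
  # analytic solution from kappa(0) = (0, -dd/om): exact circle
  exact <- c(sin(om * 4) , -cos(om * 4)) * dd / om
  err <- function(method, nstep) {
    org <- organ_state(1, 1, C = dd / om, psi_c = -pi / 2, n_segments = 1)
    d <- drv
    dt <- 4 / nstep
    for (i in seq_len(nstep)) {
      org <- advance_organ(org, d, dt, method = method)
      d <- advance_driver(d, dt)
    }
    sqrt(sum((org$kappa - exact) ^ 2))
  }
  e_eu <- c(err("euler", 400), err("euler", 800))
  e_mp <- c(err("midpoint", 400), err("midpoint", 800))
  expect_gt(e_eu[1] / e_eu[2], 1.8)   # first order: error ~ dt
  expect_gt(e_mp[1] / e_mp[2], 3.5)   # second order: error ~ dt^2
  expect_lt(e_mp[1], e_eu[1] / 10)
})
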