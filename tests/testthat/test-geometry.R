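test_that("a straight organ reconstructs as a vertical line", {
  org <- organ_state(0.5, 0.1, C = 0, psi_c = 0, n_segments = 100)
  cl <- reconstruct_centerline(org)
  expect_equal(apical_tip(org), c(0, 0, 10))
  expect_equal(cl$points[, 1:2], matrix(0, 101, 2))
  expect_equal(cl$tangents, matrix(rep(c(0, 0, 1), each = 101), 101))
})

test_that("a uniformly curved organ is a planar arc with the closed-form tip", {
  C <- 0.08; L <- 10
  org <- organ_state(0.5, L / 100, C = C, psi_c = 0, n_segments = 100)
  tip <- apical_tip(org)
  expect_equal(tip, c((1 - cos(C * L)) / C, 0, sin(C * L) / C),
               tolerance = 1e-10)
  cl <- reconstruct_centerline(org)
  expect_lt(planarity_deviation(cl), 1e-9)
  # the arc lies in the x-z plane
  expect_lt(max(abs(cl$points[, 2])), 1e-9)

  # small-curvature limit: x_a -> C L^2 / 2
  C2 <- 0.1 / L
  org2 <- organ_state(0.5, L / 100, C = C2, n_segments = 100)
  expect_equal(apical_tip(org2)[1], C2 * L ^ 2 / 2, tolerance = 1e-2)
})

test_that("frame vectors stay orthonormal and twist-free", {
  org <- organ_state(0.5, 0.1, C = 0.06,
                     psi_c = seq(0, 3, length.out = 100), n_segments = 100)
  cl <- reconstruct_centerline(org)
  norms_t <- sqrt(rowSums(cl$tangents ^ 2))
  norms_d <- sqrt(rowSums(cl$d1 ^ 2))
  dots <- rowSums(cl$tangents * cl$d1)
  expect_lt(max(abs(norms_t - 1)), 1e-9)
  expect_lt(max(abs(norms_d - 1)), 1e-9)
  expect_lt(max(abs(dots)), 1e-9)
  # zero twist: the rotation carrying frame i to frame i+1 must have its
  # axis perpendicular to the local tangent (no component of rotation
  # about t). The axis is read off the skew part of F_{i+1} F_i^T.
  for (i in seq(1, 100, by = 9)) {
    Fi <- rbind(cl$tangents[i, ], cl$d1[i, ], cl$d2[i, ])
    Fj <- rbind(cl$tangents[i + 1, ], cl$d1[i + 1, ], cl$d2[i + 1, ])
    M <- t(Fj) %*% Fi
    axis <- c(M[3, 2] - M[2, 3], M[1, 3] - M[3, 1], M[2, 1] - M[1, 2])
    expect_lt(abs(sum(axis * cl$tangents[i, ])) / sqrt(sum(axis ^ 2)),
              1e-12)
  }
})

test_that("linearly rotating curvature direction yields a helix of constant radius", {
  # constant curvature C with psi_c rotating at rate alpha per unit arc
  # length in the zero-twist frame is a circular helix with torsion alpha:
  # radius C/(C^2+alpha^2), axis (alpha t + C b)/sqrt(C^2+alpha^2). The
  # axis is anchored on an interior frame; point-to-axis distances must be
  # constant.
  C <- 0.15; alpha <- 0.8; L <- 10
  radii_spread <- function(n) {
    smid <- (seq_len(n) - 0.5) * L / n
    org <- organ_state(0.5, L / n, C = C, psi_c = wrap_angle(alpha * smid),
                       n_segments = n)
    cl <- reconstruct_centerline(org)
    wind2 <- C ^ 2 + alpha ^ 2
    r_h <- C / wind2
    i <- floor(n / 2)
    ni <- cos(alpha * cl$s[i]) * cl$d1[i, ] +
      sin(alpha * cl$s[i]) * cl$d2[i, ]
    ti <- cl$tangents[i, ]
    bi <- c(ti[2] * ni[3] - ti[3] * ni[2],
            ti[3] * ni[1] - ti[1] * ni[3],
            ti[1] * ni[2] - ti[2] * ni[1])
    a <- (alpha * ti + C * bi) / sqrt(wind2)
    rel <- sweep(cl$points, 2, cl$points[i, ] + r_h * ni)
    proj <- rel - outer(c(rel %*% a), a)
    d <- sqrt(rowSums(proj ^ 2))
    c(spread = stats::sd(d) / mean(d), bias = abs(mean(d) - r_h) / r_h,
      dev = planarity_deviation(cl))
  }
  fine <- radii_spread(4000)
  expect_lt(fine[["spread"]], 1e-6)
  expect_lt(fine[["bias"]], 1e-6)
  expect_gt(fine[["dev"]], 1e-4)   # non-planar by construction
  # discretization error is second order in the segment length
  coarse <- radii_spread(1000)
  expect_gt(coarse[["spread"]] / fine[["spread"]], 8)
})

test_that("surface fibers measured on the reconstruction obey the analytic relation", {
  org <- organ_state(0.4, 0.1, C = 0.2,
                     psi_c = seq(-1, 2, length.out = 100), n_segments = 100)
  psis <- curv_direction(org)
  for (phi_off in c(0, pi, pi / 2)) {
    # inner (phi = psi_c), outer (psi_c + pi) and lateral fibers
    measured <- vapply(seq_len(100), function(i) {
      surface_fiber_lengths(org, psis[i] + phi_off)[i]
    }, numeric(1))
    analytic <- surface_segment_length(0.1, 0.2, 0.4, 0, phi_off)
    expect_lt(max(abs(measured - analytic)), 1e-9)
  }
})

test_that("tip position converges under segment refinement", {
  tip_at <- function(n) {
    org <- organ_state(0.5, 10 / n, C = 0.08,
                       psi_c = wrap_angle(0.5 * (seq_len(n) - 0.5) * 10 / n),
                       n_segments = n)
    apical_tip(org)
  }
  t50 <- tip_at(50); t100 <- tip_at(100); t200 <- tip_at(200)
  expect_lt(sqrt(sum((t100 - t50) ^ 2)) / sqrt(sum(t100 ^ 2)), 0.01)
  expect_lt(sqrt(sum((t200 - t100) ^ 2)) / sqrt(sum(t200 ^ 2)), 0.005)
})

test_that("rotating the base director rotates the shape rigidly about z", {
  alpha <- 0.7
  psi <- seq(0, 2, length.out = 60)
  org1 <- organ_state(0.5, 0.1, C = 0.1, psi_c = psi, n_segments = 60)
  org2 <- organ_state(0.5, 0.1, C = 0.1, psi_c = wrap_angle(psi + alpha),
                      n_segments = 60)
  cl1 <- reconstruct_centerline(org1)
  cl2 <- reconstruct_centerline(org2)
  rot <- cbind(c(cos(alpha), sin(alpha), 0),
               c(-sin(alpha), cos(alpha), 0), c(0, 0, 1))
  expect_equal(cl2$points, cl1$points %*% t(rot), tolerance = 1e-9)
  # polar track view: rho unchanged, theta shifted by alpha
  st1 <- lapply(1:3, function(i) { o <- org1; o$time <- i; o })
  st2 <- lapply(1:3, function(i) { o <- org2; o$time <- i; o })
  tr1 <- track_tip(st1); tr2 <- track_tip(st2)
  expect_equal(tr2$rho, tr1$rho, tolerance = 1e-9)
  expect_equal(wrap_angle(tr2$theta - tr1$theta), rep(alpha, 3),
               tolerance = 1e-9)
})

test_that("track assembly validates time ordering", {
  org <- organ_state(0.5, 0.1, C = 0.05, n_segments = 10)
  o2 <- org; o2$time <- -1
  expect_error(track_tip(list(org, o2)), "increasing")
  expect_error(track_tip(list(org)), "length")
})

test_that("a subapical growth zone stores a helix in the frozen base", {
  sim <- sim_subapical()
  n <- length(sim$states)
  basal_dev <- function(state) {
    cl <- reconstruct_centerline(state)
    L <- organ_length(state)
    keep <- cl$s <= L - 5  # below the growth zone
    planarity_deviation(list(points = cl$points[keep, ], s = cl$s[keep]))
  }
  apical_dev <- function(state) {
    cl <- reconstruct_centerline(state)
    L <- organ_length(state)
    keep <- cl$s >= L - 5
    planarity_deviation(list(points = cl$points[keep, ], s = cl$s[keep]))
  }
  early <- sim$states[[round(n / 5)]]
  late <- sim$states[[n]]
  expect_gt(basal_dev(late), basal_dev(early))
  # the growing zone itself stays essentially planar (uniform psi_c)
  expect_lt(apical_dev(late), 1e-4)
})
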