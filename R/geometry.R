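#' Reconstruct the 3D centerline with a zero-twist frame
#'
#' Integrates the organ shape along the abscissa from the clamped base
#' (origin, tangent +z, reference director d1 = +x). Within each segment
#' the curvature is constant, so the frame is propagated by the exact
#' rotation for a circular arc: the tangent turns by `C * L` in the plane
#' spanned by the tangent and the curvature normal
#' `c = cos(psi_c) d1 + sin(psi_c) d2`, and the directors are rotated about
#' the same (binormal) axis, which transports them without twist. The
#' zero-twist (parallel-transport) frame realizes the no-torsion
#' assumption: surface lines parallel to the median stay parallel.
#'
#' @param organ an [organ_state()].
#' @return an object of class `centerline3d`: list with `s` (boundary
#'   abscissas, length n+1), `points`, `tangents`, `d1`, `d2`
#'   ((n+1) x 3 matrices).
#' @export
reconstruct_centerline <- function(organ) {
  n <- length(organ$rest_length)
  pts <- matrix(0, n + 1, 3)
  tg <- matrix(0, n + 1, 3); tg[1, ] <- c(0, 0, 1)
  d1m <- matrix(0, n + 1, 3); d1m[1, ] <- c(1, 0, 0)
  d2m <- matrix(0, n + 1, 3); d2m[1, ] <- c(0, 1, 0)
  p <- c(0, 0, 0); tv <- c(0, 0, 1); d1 <- c(1, 0, 0); d2 <- c(0, 1, 0)
  Cs <- curvature(organ)
  psis <- curv_direction(organ)
  for (i in seq_len(n)) {
    len <- organ$rest_length[i]
    C <- Cs[i]
    if (C * len < 1e-12) {
      p <- p + len * tv
    } else {
      cdir <- cos(psis[i]) * d1 + sin(psis[i]) * d2
      theta <- C * len
      p <- p + (sin(theta) / C) * tv + ((1 - cos(theta)) / C) * cdir
      axis <- c(tv[2] * cdir[3] - tv[3] * cdir[2],
                tv[3] * cdir[1] - tv[1] * cdir[3],
                tv[1] * cdir[2] - tv[2] * cdir[1])
      fr <- rotate_frame(tv, d1, d2, axis, theta)
      tv <- fr$t; d1 <- fr$d1; d2 <- fr$d2
    }
    pts[i + 1, ] <- p
    tg[i + 1, ] <- tv
    d1m[i + 1, ] <- d1
    d2m[i + 1, ] <- d2
  }
  structure(list(s = c(0, cumsum(organ$rest_length)), points = pts,
                 tangents = tg, d1 = d1m, d2 = d2m,
                 radius = organ$radius),
            class = "centerline3d")
}

#' @export
print.centerline3d <- function(x, ...) {
  tip <- x$points[nrow(x$points), ]
  cat("<centerline3d> ", nrow(x$points), "points, length",
      format(max(x$s)), "mm\n")
  cat("  tip:", paste(format(tip, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' 3D position of the apical tip
#'
#' The last point of the reconstructed centerline; its first two
#' coordinates are the horizontal projection tracked in nutation
#' experiments (gravity axis = +z). Uses a tip-only propagation of the
#' zero-twist frame (same arithmetic as [reconstruct_centerline()],
#' without storing intermediate points).
#'
#' @param organ an [organ_state()].
#' @return numeric `c(x, y, z)` (mm).
#' @export
apical_tip <- function(organ) {
  n <- length(organ$rest_length)
  p1 <- p2 <- p3 <- 0
  t1 <- 0; t2 <- 0; t3 <- 1
  a1 <- 1; a2 <- 0; a3 <- 0   # director d1
  b1 <- 0; b2 <- 1; b3 <- 0   # director d2
  Cs <- curvature(organ)
  psis <- curv_direction(organ)
  lens <- organ$rest_length
  for (i in seq_len(n)) {
    C <- Cs[i]; len <- lens[i]
    if (C * len < 1e-12) {
      p1 <- p1 + len * t1; p2 <- p2 + len * t2; p3 <- p3 + len * t3
    } else {
      cp <- cos(psis[i]); sp <- sin(psis[i])
      c1 <- cp * a1 + sp * b1; c2 <- cp * a2 + sp * b2; c3 <- cp * a3 + sp * b3
      th <- C * len
      sA <- sin(th) / C; cA <- (1 - cos(th)) / C
      p1 <- p1 + sA * t1 + cA * c1
      p2 <- p2 + sA * t2 + cA * c2
      p3 <- p3 + sA * t3 + cA * c3
      # binormal axis u = t x c (unit), rotate frame about u by th
      u1 <- t2 * c3 - t3 * c2; u2 <- t3 * c1 - t1 * c3; u3 <- t1 * c2 - t2 * c1
      ct <- cos(th); st <- sin(th)
      rot <- function(v1, v2, v3) {
        d <- u1 * v1 + u2 * v2 + u3 * v3
        w1 <- u2 * v3 - u3 * v2; w2 <- u3 * v1 - u1 * v3; w3 <- u1 * v2 - u2 * v1
        c(v1 * ct + w1 * st + u1 * d * (1 - ct),
          v2 * ct + w2 * st + u2 * d * (1 - ct),
          v3 * ct + w3 * st + u3 * d * (1 - ct))
      }
      tv <- rot(t1, t2, t3); t1 <- tv[1]; t2 <- tv[2]; t3 <- tv[3]
      av <- rot(a1, a2, a3); a1 <- av[1]; a2 <- av[2]; a3 <- av[3]
      bv <- rot(b1, b2, b3); b1 <- bv[1]; b2 <- bv[2]; b3 <- bv[3]
    }
  }
  c(p1, p2, p3)
}

#' Assemble the horizontal apical-tip track of a simulation
#'
#' @param states list of [organ_state()] with strictly increasing times.
#' @return an [apical_track()].
#' @export
track_tip <- function(states) {
  stopifnot(length(states) >= 2)
  times <- vapply(states, function(o) o$time, numeric(1))
  if (any(diff(times) <= 0)) stop("state times must be strictly increasing")
  tips <- t(vapply(states, apical_tip, numeric(3)))
  apical_track(times, tips[, 1], tips[, 2])
}

#' Deviation of a centerline from planarity
#'
#' Smallest singular value of the centered point cloud (rms distance from
#' the best-fit plane through the centroid), normalized by the organ
#' length. Exactly 0 for planar shapes; positive for helices.
#'
#' @param line a `centerline3d` (or any list with `points` and `s`).
#' @return dimensionless deviation.
#' @export
planarity_deviation <- function(line) {
  pts <- line$points
  if (nrow(pts) < 3) stop("need at least 3 points")
  ctr <- scale(pts, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  (min(sv) / sqrt(nrow(pts))) / max(line$s)
}

#' Surface fiber lengths measured on the reconstructed geometry
#'
#' For each segment, the surface fiber at cross-section angle `phi` is
#' materialized in 3D from the reconstructed frame: its endpoints are the
#' segment's boundary points offset radially by `R` along
#' `cos(phi) d1 + sin(phi) d2`. Within a segment the fiber is a circular
#' arc sweeping the same angle `theta = C * L0` as the median line, so its
#' length is recovered from the measured 3D chord as
#' `theta / (2 sin(theta/2)) * |chord|`. This is an independent geometric
#' measurement that must reproduce the analytic fiber-length relation
#' `L0 * (1 - C*R*cos(phi - psi_c))` segment by segment.
#'
#' @param organ an [organ_state()].
#' @param phi cross-section angle (rad).
#' @return numeric vector of fiber lengths (mm) per segment.
#' @export
surface_fiber_lengths <- function(organ, phi) {
  cl <- reconstruct_centerline(organ)
  n <- length(organ$rest_length)
  R <- organ$radius
  off <- cos(phi) * cl$d1 + sin(phi) * cl$d2   # (n+1) x 3 radial offsets
  q <- cl$points + R * off
  chord <- sqrt(rowSums((q[-1, , drop = FALSE] -
                           q[-(n + 1), , drop = FALSE]) ^ 2))
  theta <- curvature(organ) * organ$rest_length
  fac <- ifelse(theta < 1e-8, 1, theta / (2 * sin(theta / 2)))
  chord * fac
}
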