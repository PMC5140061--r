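#' Discrete organ state
#'
#' A growing plant organ is modelled as a cylinder of constant radius `R`,
#' discretized into ordered material segments from base (s = 0) to apex
#' (s = L). Each segment carries a rest length (mm), a curvature magnitude
#' `C` (1/mm) and a curvature direction `psi_c` (rad), the cross-section
#' angle of the principal direction of curvature measured from the
#' transported reference director.
#'
#' Internally the per-segment curvature is stored as the dimensionless
#' curvature vector `kappa = C*R * (cos psi_c, sin psi_c)`, which is regular
#' at C = 0 where the direction is undefined; `C` and `psi_c` are derived
#' views. For a straight segment `psi_c` is reported as the direction of the
#' last nonzero curvature vector (0 for a never-curved segment); that value
#' never enters the dynamics.
#'
#' @param radius organ radius R (mm).
#' @param rest_length segment rest lengths (mm), base to apex. A scalar is
#'   recycled to `n_segments`.
#' @param C curvature magnitude per segment (1/mm), recycled.
#' @param psi_c curvature direction per segment (rad), recycled.
#' @param time simulation time (s) attached to this state.
#' @param n_segments number of segments when scalars are given.
#' @return an object of class `organ_state`.
#' @examples
#' org <- organ_state(radius = 0.5, rest_length = 10 / 100, C = 0.02,
#'                    psi_c = 0, n_segments = 100)
#' organ_length(org)
#' @export
organ_state <- function(radius, rest_length, C = 0, psi_c = 0, time = 0,
                        n_segments = max(length(rest_length), length(C),
                                         length(psi_c))) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0)
  rest_length <- rep_len(as.numeric(rest_length), n_segments)
  C <- rep_len(as.numeric(C), n_segments)
  psi_c <- rep_len(as.numeric(psi_c), n_segments)
  if (any(rest_length <= 0)) stop("all segment rest lengths must be > 0")
  if (any(C < 0)) stop("curvature C must be >= 0")
  if (any(C * radius >= 1)) {
    stop("invalid geometry: C*R >= 1 (inner surface fiber length nonpositive)")
  }
  k <- C * radius
  obj <- list(
    radius = radius,
    time = time,
    rest_length = rest_length,
    kappa = cbind(k * cos(psi_c), k * sin(psi_c)),
    psi_memory = ifelse(k > 0, wrap_angle(psi_c), 0)
  )
  class(obj) <- "organ_state"
  obj
}

#' @export
print.organ_state <- function(x, ...) {
  cat("<organ_state>  t =", format(x$time), "s\n")
  cat("  segments:", length(x$rest_length),
      " length:", format(organ_length(x)), "mm",
      " radius:", format(x$radius), "mm\n")
  cat("  max C*R:", format(max(rowSums(x$kappa^2))^0.5), "\n")
  invisible(x)
}

#' Total organ length
#' @param organ an `organ_state`.
#' @return total rest length L (mm).
#' @export
organ_length <- function(organ) sum(organ$rest_length)

#' Base-anchored curvilinear abscissa of each segment
#'
#' The abscissa of segment i is the cumulative sum of the preceding rest
#' lengths, i.e. the arc-length position of the segment's basal boundary.
#'
#' @param organ an `organ_state`.
#' @return numeric vector of length `n_segments`.
#' @export
abscissa <- function(organ) {
  c(0, cumsum(organ$rest_length))[seq_along(organ$rest_length)]
}

#' Per-segment curvature magnitude (1/mm)
#' @param organ an `organ_state`.
#' @export
curvature <- function(organ) sqrt(rowSums(organ$kappa^2)) / organ$radius

#' Per-segment curvature direction (rad, in (-pi, pi])
#'
#' Undefined at C = 0; there the remembered direction of the last nonzero
#' curvature vector is reported (0 for a never-curved segment).
#' @param organ an `organ_state`.
#' @export
curv_direction <- function(organ) {
  k <- sqrt(rowSums(organ$kappa^2))
  ifelse(k > 0, atan2(organ$kappa[, 2], organ$kappa[, 1]), organ$psi_memory)
}

#' @export
as.data.frame.organ_state <- function(x, ...) {
  data.frame(
    s = abscissa(x),
    rest_length = x$rest_length,
    C = curvature(x),
    psi_c = curv_direction(x)
  )
}

#' Length of a surface fiber of a curved cylindrical segment
#'
#' For a segment of median rest length `L0`, curvature `C` in direction
#' `psi_c`, the fiber running along the surface at cross-section angle `phi`
#' has length `L0 * (1 - C*R*cos(phi - psi_c))`: shortest on the inner
#' (concave) side `phi = psi_c`, longest on the outer side `phi = psi_c + pi`.
#'
#' @param L0 median (centerline) length of the segment (mm).
#' @param C curvature (1/mm), `C*R < 1`.
#' @param R organ radius (mm).
#' @param psi_c curvature direction (rad).
#' @param phi cross-section angle(s) of the fiber (rad).
#' @return fiber length(s) (mm).
#' @export
surface_segment_length <- function(L0, C, R, psi_c, phi) {
  stopifnot(L0 > 0, C >= 0, R > 0)
  if (any(C * R >= 1)) {
    stop("invalid geometry: C*R >= 1 (inner surface fiber length nonpositive)")
  }
  L0 * (1 - C * R * cos(phi - psi_c))
}

#' Finite elongation strain of surface fibers between two configurations
#'
#' The strain at angle `phi` is the relative length change of the surface
#' fiber, `eps(phi) = Ls'(phi) / Ls(phi) - 1`, computed from the fiber
#' lengths of the segment before and after deformation. This is the exact
#' finite-deformation quantity and serves as the brute-force oracle for the
#' strain-rate field used by the time stepper.
#'
#' @param before,after lists (or numeric vectors) with elements `L0`, `C`,
#'   `psi_c` describing the segment before/after.
#' @param R organ radius (mm).
#' @param phi cross-section angle(s) (rad).
#' @return dimensionless strain(s) at `phi`.
#' @examples
#' finite_strain(list(L0 = 1, C = 0, psi_c = 0),
#'               list(L0 = 1.1, C = 0, psi_c = 0), R = 0.5, phi = 0)
#' @export
finite_strain <- function(before, after, R, phi) {
  b <- as.list(before); a <- as.list(after)
  ls0 <- surface_segment_length(b$L0, b$C, R, b$psi_c, phi)
  ls1 <- surface_segment_length(a$L0, a$C, R, a$psi_c, phi)
  ls1 / ls0 - 1
}
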