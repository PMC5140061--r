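# Small numeric helpers shared across the package.

#' Wrap angles into (-pi, pi]
#'
#' @param a numeric vector of angles (rad).
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Unwrap an angle series
#'
#' Removes 2*pi jumps so consecutive samples never differ by more than pi.
#' Thin wrapper over [signal::unwrap()] so every module shares one convention.
#'
#' @param a numeric vector of angles (rad), possibly wrapped.
#' @return unwrapped angle series.
#' @export
unwrap_angle <- function(a) {
  if (anyNA(a)) {
    # unwrap the observed run, keep NA positions
    out <- a
    ok <- !is.na(a)
    if (any(ok)) out[ok] <- signal::unwrap(a[ok])
    return(out)
  }
  signal::unwrap(a)
}

# Rotate the orthonormal frame (t, d1, d2) about unit axis `axis` by `angle`
# using the Rodrigues formula. Vectors are length-3 numerics.
rotate_frame <- function(tv, d1, d2, axis, angle) {
  rot <- function(v) {
    ca <- cos(angle); sa <- sin(angle)
    cr <- c(axis[2] * v[3] - axis[3] * v[2],
            axis[3] * v[1] - axis[1] * v[3],
            axis[1] * v[2] - axis[2] * v[1])
    v * ca + cr * sa + axis * sum(axis * v) * (1 - ca)
  }
  list(t = rot(tv), d1 = rot(d1), d2 = rot(d2))
}

# Indices of strict local maxima of x (interior points only).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

# Principal-axis angle (mod pi) of a planar point cloud: the direction of the
# leading eigenvector of the centered covariance. Used for ellipse orientation.
principal_axis_angle <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  m <- cbind(xc, yc)
  ev <- eigen(crossprod(m) / nrow(m), symmetric = TRUE)
  v <- ev$vectors[, 1]
  atan2(v[2], v[1]) %% pi
}

# FNV-1a 32-bit hash of a string; used to stamp output files with a config
# fingerprint. Arithmetic is done in doubles, kept exact by splitting the
# 32-bit state before multiplying.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
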