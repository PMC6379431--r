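# Small vector/rotation helpers shared across modules. All angles in degrees,
# all coordinates in Angstrom.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps^0.5) stop("cannot normalize a zero-length vector")
  v / n
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation: proper rotation by `angle` degrees about `axis`
#' (right-hand rule). Used by the synthetic generators to apply kinks and by
#' tests to construct known rigid motions.
#'
#' @param axis 3-vector; normalized internally.
#' @param angle rotation angle in degrees.
#' @return 3x3 proper orthogonal matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- .unit(axis)
  th <- .deg2rad(angle)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Proper rotation carrying unit vector a onto unit vector b.
.rotation_between <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (sqrt(sum(v^2)) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any axis perpendicular to a
    perp <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- .unit(perp - sum(perp * a) * a)
    return(rotation_about_axis(perp, 180))
  }
  K <- matrix(c(0, v[3], -v[2],
                -v[3], 0, v[1],
                v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Angle between two directions
#'
#' @param a,b 3-vectors (need not be unit length).
#' @return angle in degrees in [0, 180].
#' @export
angle_between <- function(a, b) {
  d <- sum(.unit(a) * .unit(b))
  .rad2deg(acos(min(1, max(-1, d))))
}

#' Random proper rotation
#'
#' Uniform random rotation (QR of a Gaussian matrix with sign fix), for
#' invariance tests. Deterministic given the current RNG state.
#'
#' @param seed optional integer seed.
#' @return 3x3 proper orthogonal matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  Q <- Q %*% diag(sign(d))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# coordinate matrix (n x 3) from an atoms data frame
.coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}
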