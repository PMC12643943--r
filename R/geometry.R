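# Low-level 3D geometry used by the backbone builder, torsion
# measurement and ring closure. Angles are in degrees everywhere at the
# interface; radians never leak out of this file.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))
.unit <- function(v) v / .vnorm(v)
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap angles onto the torsion range (-180, 180]
#'
#' Degrees in, degrees out; the guards keep values at the boundary in
#' range when `x/360` rounds at the representation limit.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Wrapped angles in `(-180, 180]`.
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * round(x / 360)
  w[!is.na(w) & w <= -180] <- w[!is.na(w) & w <= -180] + 360
  w[!is.na(w) & w > 180] <- w[!is.na(w) & w > 180] - 360
  w
}

# Bond angle a-b-c in degrees.
bond_angle <- function(a, b, c) {
  u <- .unit(a - b); v <- .unit(c - b)
  acos(pmin(1, pmax(-1, sum(u * v)))) * .rad2deg
}

# Signed dihedral a-b-c-d in degrees on (-180, 180].
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  wrap_angle(atan2(y, x) * .rad2deg)
}

# Natural-extension (NeRF) placement: position atom d given the three
# preceding atoms a-b-c, the bond length c-d, the angle b-c-d and the
# dihedral a-b-c-d (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * .deg2rad
  tor <- torsion * .deg2rad
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  M <- cbind(bc, m, n)
  as.vector(M %*% d2) + c
}

# Rotation matrix for angle theta (radians) about unit axis u (Rodrigues).
rotation_about_axis <- function(u, theta) {
  u <- .unit(u)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Random proper rotation, uniform over SO(3), from a normalized
# quaternion.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / .vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Apply a rigid motion to a structure or coordinate matrix
#'
#' Rotates (about the origin) and translates all coordinates. Accepts a
#' plain n x 3 matrix, a [macrocycle_structure()] or a complex as read by
#' [read_backbone_pdb()].
#'
#' @param x Coordinates, macrocycle or complex structure.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation Length-3 numeric vector (Angstrom).
#' @return Object of the same type with transformed coordinates.
#' @export
rigid_transform <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  tr <- function(m) sweep(m %*% rotation, 2, -translation)
  if (is.matrix(x)) return(tr(x))
  if (inherits(x, "macrocycle_structure")) {
    for (at in dimnames(x$coords)[[2]]) {
      m <- x$coords[, at, , drop = FALSE]
      dim(m) <- c(dim(x$coords)[1], 3)
      ok <- !is.na(m[, 1])
      m[ok, ] <- tr(m[ok, , drop = FALSE])
      x$coords[, at, ] <- m
    }
    return(x)
  }
  if (inherits(x, "complex_structure")) {
    x$binder <- rigid_transform(x$binder, rotation, translation)
    x$atoms[, c("x", "y", "z")] <-
      tr(as.matrix(x$atoms[, c("x", "y", "z")]))
    return(x)
  }
  stop("unsupported type for rigid_transform")
}
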