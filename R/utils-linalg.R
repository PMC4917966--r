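# Small 3-vector helpers shared across the geometry and solver code.
# All angles are degrees at the user surface; radians internally.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero 3-vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of `angle` degrees
#' about `axis` (need not be unit length).
#'
#' @param axis numeric 3-vector, rotation axis.
#' @param angle rotation angle in degrees (right-handed about `axis`).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle) {
  u <- unit3(axis)
  th <- angle * DEG
  K <- matrix(c(0, u[3L], -u[2L],
                -u[3L], 0, u[1L],
                u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @rdname rotation_about
#' @export
rotation_z <- function(angle) rotation_about(c(0, 0, 1), angle)

# angle between two vectors, degrees in [0, 180]
vec_angle <- function(u, v) {
  u <- unit3(u); v <- unit3(v)
  # atan2 form is numerically stable near 0 and 180
  atan2(vnorm(cross3(u, v)), sum(u * v)) / DEG
}

# cylindrical radius of a point (distance from the fivefold z-axis)
cyl_radius <- function(p) sqrt(p[1L]^2 + p[2L]^2)

# spherical direction from polar angle (from +z) and azimuth, both degrees
dir_from_polar <- function(polar, azimuth) {
  c(sin(polar * DEG) * cos(azimuth * DEG),
    sin(polar * DEG) * sin(azimuth * DEG),
    cos(polar * DEG))
}
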