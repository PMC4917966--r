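#' Helix segment
#'
#' A coarse-grained alpha-helix represented as a straight elastic rod: an axis
#' point (segment midpoint), a unit direction oriented from the N-terminal to
#' the C-terminal end, a length and a rod diameter (5 Angstrom by default, the
#' effective backbone envelope of a TM helix).
#'
#' @param subunit_index integer 0-4, subunit the helix belongs to.
#' @param name one of "NTERM", "TM1", "TM2".
#' @param residue_range integer length-2, 1-based inclusive (start, end).
#' @param axis_point numeric 3-vector, segment midpoint (Angstrom).
#' @param axis_direction numeric 3-vector, unit direction N-end to C-end.
#' @param length segment length in Angstrom.
#' @param rod_diameter rod diameter in Angstrom (default 5).
#' @return object of class `helix_segment`.
#' @export
helix_segment <- function(subunit_index, name, residue_range, axis_point,
                          axis_direction, length, rod_diameter = 5) {
  name <- match.arg(name, c("NTERM", "TM1", "TM2"))
  stopifnot(subunit_index %in% 0:4,
            length(residue_range) == 2L, residue_range[1L] <= residue_range[2L],
            length > 0, rod_diameter > 0)
  axis_direction <- as.numeric(axis_direction)
  if (abs(vnorm(axis_direction) - 1) > 1e-9)
    axis_direction <- unit3(axis_direction)
  structure(list(subunit_index = as.integer(subunit_index),
                 name = name,
                 residue_range = as.integer(residue_range),
                 axis_point = as.numeric(axis_point),
                 axis_direction = axis_direction,
                 length = as.numeric(length),
                 rod_diameter = as.numeric(rod_diameter)),
            class = "helix_segment")
}

#' @export
print.helix_segment <- function(x, ...) {
  cat(sprintf("<helix_segment> %s subunit %d  res %d-%d  L=%.1f A  dir=(%.3f, %.3f, %.3f)\n",
              x$name, x$subunit_index, x$residue_range[1L], x$residue_range[2L],
              x$length, x$axis_direction[1L], x$axis_direction[2L],
              x$axis_direction[3L]))
  invisible(x)
}

# N-terminal and C-terminal end points of the rod axis
segment_ends <- function(seg) {
  h <- seg$length / 2
  list(n = seg$axis_point - h * seg$axis_direction,
       c = seg$axis_point + h * seg$axis_direction)
}

# apply rigid-body transform x -> R x + t to a segment
transform_segment <- function(seg, R = diag(3), t = c(0, 0, 0)) {
  seg$axis_point <- as.numeric(R %*% seg$axis_point + t)
  seg$axis_direction <- as.numeric(R %*% seg$axis_direction)
  seg
}

#' Fit a helix axis by total least squares
#'
#' Fits a straight axis to backbone coordinates (typically C-alpha atoms of
#' one helix) as the total-least-squares line: the first principal axis of
#' the centred coordinates. The direction is oriented from the first
#' coordinate (N-terminal end) to the last, and the length is the span of the
#' coordinate projections onto the axis.
#'
#' @param coords numeric matrix, n x 3, ordered N-terminal to C-terminal.
#' @return list with `axis_point` (centroid), `axis_direction` (unit,
#'   oriented N to C), `length` (projection span, Angstrom) and `rmsd`
#'   (root-mean-square perpendicular distance of the points to the axis).
#' @export
fit_helix_axis <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (n < 4L) stop("degenerate input: need at least 4 backbone coordinates, got ", n)
  ctr <- colMeans(coords)
  X <- sweep(coords, 2L, ctr)
  if (max(abs(X)) < 1e-9) stop("degenerate input: coordinates are coincident")
  sv <- svd(X, nu = 0L, nv = 3L)
  dir <- sv$v[, 1L]
  # orient N -> C using the chord between terminal coordinates
  chord <- coords[n, ] - coords[1L, ]
  if (sum(dir * chord) < 0) dir <- -dir
  proj <- X %*% dir
  perp2 <- rowSums(X^2) - as.numeric(proj)^2
  list(axis_point = ctr,
       axis_direction = as.numeric(dir),
       length = as.numeric(max(proj) - min(proj)),
       rmsd = sqrt(mean(pmax(perp2, 0))))
}

# closest points of two infinite lines (point p + s*d); returns parameters
line_closest_parameters <- function(p1, d1, p2, d2) {
  w0 <- p1 - p2
  a <- sum(d1 * d1); b <- sum(d1 * d2); cc <- sum(d2 * d2)
  d <- sum(d1 * w0); e <- sum(d2 * w0)
  den <- a * cc - b * b
  if (abs(den) < 1e-12) {            # parallel lines
    s <- 0
    t <- e / cc
  } else {
    s <- (b * e - cc * d) / den
    t <- (a * e - b * d) / den
  }
  c(s = s, t = t)
}

#' Signed crossing angle between two helix axes
#'
#' Angle between the two N-to-C axis directions, signed by the packing
#' handedness: viewed along the common perpendicular between the two axes, a
#' pair related by a right-handed rotation is negative. The convention is
#' calibrated on the pentamer geometry so that the adjacent-subunit TM1-TM1
#' pair reads about -43 degrees and the adjacent TM1/TM2 contact pair reads
#' slightly positive (~+10 degrees) in the reduced form.
#'
#' @param a,b `helix_segment` objects.
#' @param reduce if TRUE, reduce to the conventional packing range (-90, 90]
#'   (axes treated as undirected lines); default FALSE returns the full
#'   (-180, 180] angle between directed axes.
#' @return signed angle in degrees; symmetric in its arguments.
#' @export
crossing_angle <- function(a, b, reduce = FALSE) {
  u <- a$axis_direction; v <- b$axis_direction
  if (a$length <= 0 || b$length <= 0) stop("zero-length axis")
  ang <- vec_angle(u, v)
  cr <- cross3(u, v)
  if (vnorm(cr) < 1e-9) {                       # parallel or antiparallel
    return(if (ang < 90) 0 else 180)
  }
  # common perpendicular, oriented from axis a to axis b
  st <- line_closest_parameters(a$axis_point, u, b$axis_point, v)
  w <- (b$axis_point + st[["t"]] * v) - (a$axis_point + st[["s"]] * u)
  if (vnorm(w) < 1e-9) w <- cr                  # intersecting axes: use u x v
  sgn <- if (sum(cr * w) >= 0) -1 else 1        # right-handed pair -> negative
  out <- sgn * ang
  if (reduce) {
    if (out > 90) out <- out - 180
    if (out <= -90) out <- out + 180
  }
  out
}

#' Unsigned inter-helix angle
#'
#' Plain arccosine angle between the two N-to-C axis directions, in
#' `[0, 180]` degrees. Collinear continuation of one helix by another (as in
#' the open-state N-term/TM1 contiguous helix) reads 180 degrees.
#'
#' @param a,b `helix_segment` objects.
#' @return angle in degrees.
#' @export
interhelix_angle <- function(a, b) {
  if (a$length <= 0 || b$length <= 0) stop("zero-length axis")
  vec_angle(a$axis_direction, b$axis_direction)
}

#' Closest approach between two helix rods
#'
#' Minimum Euclidean distance between the two finite axis segments (not the
#' infinite lines), i.e. the centerline-to-centerline gap.
#'
#' @param a,b `helix_segment` objects.
#' @return distance in Angstrom.
#' @export
closest_approach <- function(a, b) {
  ea <- segment_ends(a); eb <- segment_ends(b)
  segment_segment_distance(ea$n, ea$c, eb$n, eb$c)
}

# minimum distance between finite segments [p1,q1] and [p2,q2]
segment_segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2
  st <- line_closest_parameters(p1, d1, p2, d2)
  s <- min(max(st[["s"]], 0), 1)
  t <- min(max(st[["t"]], 0), 1)
  # clamped parameters are not jointly optimal in general: polish by
  # alternating point-to-segment projections (converges for convex problem)
  for (i in 1:25) {
    pa <- p1 + s * d1
    t_new <- sum((pa - p2) * d2) / sum(d2 * d2)
    t_new <- min(max(t_new, 0), 1)
    pb <- p2 + t_new * d2
    s_new <- sum((pb - p1) * d1) / sum(d1 * d1)
    s_new <- min(max(s_new, 0), 1)
    if (abs(s_new - s) < 1e-12 && abs(t_new - t) < 1e-12) {
      s <- s_new; t <- t_new
      break
    }
    s <- s_new; t <- t_new
  }
  vnorm((p1 + s * d1) - (p2 + t * d2))
}

#' Ideal alpha-helix backbone coordinates
#'
#' Generates C-alpha coordinates of an ideal alpha-helix wound about a given
#' axis: 100 degrees twist and 1.5 Angstrom rise per residue, 2.3 Angstrom
#' helical radius by default. Used to build synthetic structure fixtures and
#' as the constructive oracle for axis fitting.
#'
#' @param n_res number of residues.
#' @param axis_point point on the helix axis where residue 1's axial position
#'   starts.
#' @param axis_direction axis direction (will be normalized), N to C.
#' @param twist degrees per residue (default 100).
#' @param rise axial rise per residue in Angstrom (default 1.5).
#' @param radius helical radius in Angstrom (default 2.3).
#' @param phase azimuthal phase of residue 1 in degrees.
#' @return n_res x 3 matrix of coordinates.
#' @export
ideal_helix_coords <- function(n_res, axis_point = c(0, 0, 0),
                               axis_direction = c(0, 0, 1),
                               twist = 100, rise = 1.5, radius = 2.3,
                               phase = 0) {
  stopifnot(n_res >= 1)
  d <- unit3(axis_direction)
  # orthonormal frame (e1, e2, d)
  ref <- if (abs(d[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit3(cross3(ref, d))
  e2 <- cross3(d, e1)
  k <- seq_len(n_res) - 1L
  ang <- (phase + k * twist) * DEG
  t(vapply(seq_len(n_res), function(i) {
    axis_point + k[i] * rise * d +
      radius * (cos(ang[i]) * e1 + sin(ang[i]) * e2)
  }, numeric(3L)))
}
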