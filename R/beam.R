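# Corotational small-strain beam element for the helix rods, plus the
# nonlinear wire (spring) and hinge-connector kinematics. All stiffnesses
# are expressed as ratios to the protein Young's modulus E, lengths in
# Angstrom, forces in units of E x Angstrom^2.

# rotation vector -> rotation matrix (Rodrigues), allocation-lean
rot_exp <- function(v) {
  x <- v[1L]; y <- v[2L]; z <- v[3L]
  th2 <- x * x + y * y + z * z
  th <- sqrt(th2)
  if (th < 1e-10) {
    a <- 1; b <- 0.5
  } else {
    a <- sin(th) / th
    b <- (1 - cos(th)) / th2
  }
  matrix(c(1 - b * (y * y + z * z), a * z + b * x * y, -a * y + b * x * z,
           -a * z + b * x * y, 1 - b * (x * x + z * z), a * x + b * y * z,
           a * y + b * x * z, -a * x + b * y * z, 1 - b * (x * x + y * y)),
         3L, 3L)
}

# rotation matrix -> rotation vector (inverse of rot_exp), |v| < pi assumed
rot_log <- function(R) {
  ct <- (R[1L] + R[5L] + R[9L] - 1) / 2
  ct <- min(max(ct, -1), 1)
  th <- acos(ct)
  ax <- c(R[6L] - R[8L], R[7L] - R[3L], R[2L] - R[4L])
  if (th < 1e-8) return(ax / 2)
  if (th > pi - 1e-3) {
    # near-pi branch via the symmetric part
    B <- (R + diag(3L)) / 2
    u <- sqrt(pmax(diag(B), 0))
    k <- which.max(u)
    u <- B[, k] / B[k, k] * u[k]
    u <- unit3(u)
    # fix sign from the skew part
    if (sum(ax * u) < 0) u <- -u
    return(th * u)
  }
  (th / (2 * sin(th))) * ax
}

#' Beam section properties for a circular rod
#'
#' Axial, bending and torsional section constants of a solid circular rod of
#' the given diameter, scaled by a dimensionless stiffness ratio (the rod
#' modulus in units of the overall protein modulus E). Poisson ratio 0.3.
#'
#' @param diameter rod diameter (Angstrom).
#' @param stiffness_ratio rod modulus / protein modulus (default 1).
#' @return list with `EA`, `EI`, `GJ`, `A`, `I`, `W` (section modulus).
#' @export
rod_section <- function(diameter = 5, stiffness_ratio = 1) {
  A <- pi * diameter^2 / 4
  I <- pi * diameter^4 / 64
  G <- stiffness_ratio / (2 * (1 + 0.3))
  list(EA = stiffness_ratio * A, EI = stiffness_ratio * I, GJ = G * 2 * I,
       A = A, I = I, W = I / (diameter / 2))
}

# rest triad for an element: col 1 along the axis
element_triad <- function(dir) {
  e1 <- unit3(dir)
  ref <- if (abs(e1[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- unit3(cross3(ref, e1))
  cbind(e1, e2, cross3(e1, e2))
}

# local 7x7 stiffness (u, phi_i (3), phi_j (3))
local_stiffness <- function(el) {
  K <- matrix(0, 7L, 7L)
  L <- el$L0
  K[1L, 1L] <- el$EA / L
  K[c(2L, 5L), c(2L, 5L)] <- el$GJ / L * matrix(c(1, -1, -1, 1), 2L)
  Kb <- 2 * el$EI / L * matrix(c(2, 1, 1, 2), 2L)
  K[c(3L, 6L), c(3L, 6L)] <- Kb
  K[c(4L, 7L), c(4L, 7L)] <- Kb
  K
}

# Corotational internal force of one beam element.
# d12: (u_i, theta_i, u_j, theta_j); X0i/X0j rest positions; el carries the
# rest triad E0 and section constants. Returns global forces (12), local
# force vector f_l (7) and current length.
beam_internal_force <- function(d12, X0i, X0j, el) {
  thi <- d12[4:6]; thj <- d12[10:12]
  dx1 <- X0j[1L] + d12[7L] - X0i[1L] - d12[1L]
  dx2 <- X0j[2L] + d12[8L] - X0i[2L] - d12[2L]
  dx3 <- X0j[3L] + d12[9L] - X0i[3L] - d12[3L]
  ln <- sqrt(dx1 * dx1 + dx2 * dx2 + dx3 * dx3)
  g1 <- c(dx1, dx2, dx3) / ln
  Rm <- rot_exp((thi + thj) / 2)
  E0 <- el$E0
  m2 <- Rm %*% E0[, 2L]
  g2 <- m2 - sum(m2 * g1) * g1
  n2 <- sqrt(sum(g2 * g2))
  if (n2 < 1e-6) {
    m3 <- Rm %*% E0[, 3L]
    g3 <- unit3(m3 - sum(m3 * g1) * g1)
    g2 <- cross3(g3, g1)
  } else g2 <- g2 / n2
  g3 <- cross3(g1, g2)
  G <- matrix(c(g1, g2, g3), 3L, 3L)
  phi_i <- rot_log(crossprod(G, rot_exp(thi) %*% E0))
  phi_j <- rot_log(crossprod(G, rot_exp(thj) %*% E0))
  p <- c(ln - el$L0, phi_i, phi_j)
  f_l <- el$Kl %*% p
  dim(f_l) <- NULL

  # variation of the local dofs (corotational B matrix, moderate-rotation
  # approximation): du = g1 . (dxj - dxi);
  # dw_frame = (g1 x (dxj - dxi))/ln + g1 g1.(dthi + dthj)/2
  # dphi_i = G^T (dthi - dw_frame), same for j.
  mi <- G %*% f_l[2:4]; dim(mi) <- NULL   # nodal moments in global frame
  mj <- G %*% f_l[5:7]; dim(mj) <- NULL
  N <- f_l[1L]
  msum <- mi + mj
  fspin <- cross3(msum, g1) / ln          # frame-spin coupling
  fj <- N * g1 - fspin
  tw <- sum(msum * g1) / 2                # twist-spin share
  twg <- tw * g1
  list(F = c(-fj, mi - twg, fj, mj - twg), f_l = f_l, ln = ln)
}

# element tangent by central finite differences of the internal force
# (central keeps the noise floor ~1e-9, needed because the assembled system
# mixes stiff rods with deliberately soft mechanism modes)
beam_element_tangent <- function(d12, X0i, X0j, el, h = 1e-6) {
  F0 <- beam_internal_force(d12, X0i, X0j, el)$F
  K <- matrix(0, 12L, 12L)
  for (k in 1:12) {
    dp <- d12; dm <- d12
    dp[k] <- dp[k] + h; dm[k] <- dm[k] - h
    K[, k] <- (beam_internal_force(dp, X0i, X0j, el)$F -
                 beam_internal_force(dm, X0i, X0j, el)$F) / (2 * h)
  }
  list(F = F0, K = K)
}

#' Beam element response (cantilever-grade constitutive core)
#'
#' Internal force and consistent tangent of a single corotational beam
#' element given its 12 end displacements/rotations. Pure function; used by
#' the assembled solver and directly testable against Euler-Bernoulli
#' closed forms.
#'
#' @param element list with `L0` (rest length), `E0` (3x3 rest triad,
#'   column 1 along the axis), and section constants `EA`, `EI`, `GJ`
#'   (e.g. from [rod_section()]), plus rest end positions `X0i`, `X0j`.
#' @param d12 numeric 12-vector: (u_i, theta_i, u_j, theta_j),
#'   displacements in Angstrom, rotation vectors in radians.
#' @return list with `F` (12 internal force components, conjugate to
#'   `d12`), `f_l` (local force resultants: axial force, end moments) and
#'   `K` (12x12 tangent).
#' @export
beam_element_response <- function(element, d12) {
  el <- element
  if (is.null(el$Kl)) el$Kl <- local_stiffness(el)
  out <- beam_element_tangent(d12, el$X0i, el$X0j, el)
  fl <- beam_internal_force(d12, el$X0i, el$X0j, el)
  list(F = out$F, f_l = fl$f_l, K = out$K)
}

# --- nonlinear wire (spring) -------------------------------------------------

# force magnitude from a force-extension table: monotone cubic (Fritsch-
# Carlson) interpolation, so the force law is C1 and Newton models it well;
# linear extrapolation beyond the table, tension-only optional
spring_force_magnitude <- function(ext, table, tension_only = TRUE,
                                   fun = NULL) {
  if (tension_only && ext <= 0) return(c(f = 0, k = 0))
  x <- table[, 1L]; y <- table[, 2L]
  n <- length(x)
  if (ext <= x[1L]) {
    sl <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    return(c(f = y[1L] + sl * (ext - x[1L]), k = sl))
  }
  if (ext >= x[n]) {
    sl <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
    return(c(f = y[n] + sl * (ext - x[n]), k = sl))
  }
  if (is.null(fun)) fun <- stats::splinefun(x, y, method = "monoH.FC")
  c(f = fun(ext), k = fun(ext, deriv = 1L))
}

# internal force and tangent of a two-node wire; positions xi, xj current
spring_response <- function(xi, xj, rest_len, table, tension_only = TRUE,
                            fun = NULL) {
  dx <- xj - xi
  dist <- vnorm(dx)
  if (dist < 1e-9) {
    return(list(F = numeric(6L), K = matrix(0, 6L, 6L), ext = -rest_len))
  }
  u <- dx / dist
  ext <- dist - rest_len
  fk <- spring_force_magnitude(ext, table, tension_only, fun)
  f <- fk[["f"]]; kt <- fk[["k"]]
  Fi <- f * u; Fj <- -f * u       # tension pulls the nodes together
  uu <- tcrossprod(u)
  Kjj <- kt * uu + (f / dist) * (diag(3L) - uu)
  K <- rbind(cbind(Kjj, -Kjj), cbind(-Kjj, Kjj))
  # residual convention: internal force opposing displacement
  list(F = c(-Fi, -Fj), K = K, ext = ext, force = f)
}

# --- hinge connector ---------------------------------------------------------

# Relative-rotation energy of a hinge: rotations about the free axis cost
# k_free, all other relative rotation costs k_lock. Rotation vectors are the
# node dofs; the relative rotation is exact (matrix log).
hinge_energy <- function(tha, thb, axis, k_lock, k_free) {
  r <- rot_log(crossprod(rot_exp(thb), rot_exp(tha)))
  r_par <- sum(r * axis)
  r_perp <- r - r_par * axis
  0.5 * k_lock * sum(r_perp^2) + 0.5 * k_free * r_par^2
}

# gradient (6) and tangent (6x6) of the hinge energy by finite differences
hinge_response <- function(tha, thb, axis, k_lock, k_free, h = 1e-6) {
  d0 <- c(tha, thb)
  W <- function(d) hinge_energy(d[1:3], d[4:6], axis, k_lock, k_free)
  g <- numeric(6L)
  for (k in 1:6) {
    dp <- d0; dm <- d0
    dp[k] <- dp[k] + h; dm[k] <- dm[k] - h
    g[k] <- (W(dp) - W(dm)) / (2 * h)
  }
  K <- matrix(0, 6L, 6L)
  for (k in 1:6) {
    dp <- d0; dp[k] <- dp[k] + h
    gp <- numeric(6L)
    for (m in 1:6) {
      dpp <- dp; dpm <- dp
      dpp[m] <- dpp[m] + h; dpm[m] <- dpm[m] - h
      gp[m] <- (W(dpp) - W(dpm)) / (2 * h)
    }
    K[, k] <- (gp - g) / h
  }
  list(F = g, K = (K + t(K)) / 2)
}
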