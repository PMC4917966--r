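# Bilayer continuum: depth-resolved lateral pressure profile, tension-driven
# areal stretch and thinning, and conversion of the profile into distributed
# loads on membrane-embedded rods. Everything is nondimensional: stresses are
# expressed in units of the protein Young's modulus E, and the applied
# membrane tension enters as sigma* = stress / E.

#' Bilayer patch
#'
#' Annular membrane continuum surrounding the channel: rest thickness,
#' head/interface band widths, areal elasticity and the applied
#' nondimensional tension. The membrane is not independently meshed; it acts
#' on the protein through the lateral-pressure loads and the van der Waals
#' surface law.
#'
#' @param inner_radius protein boundary radius (Angstrom).
#' @param outer_radius far-field radius (Angstrom).
#' @param rest_thickness rest bilayer thickness h0 (Angstrom, default 33.3).
#' @param areal_modulus nondimensional areal stiffness K_A* relating tension
#'   to areal stretch, `stretch = 1 + sigma* / K_A*`.
#' @param head_width headgroup band width (Angstrom).
#' @param interface_width interfacial band width (Angstrom).
#' @param sigma_star applied nondimensional tension (>= 0).
#' @param boundary_layer decay length of the thickness boundary layer at the
#'   protein (Angstrom).
#' @return object of class `bilayer_patch`.
#' @export
bilayer_patch <- function(inner_radius = 25, outer_radius = 200,
                          rest_thickness = 33.3, areal_modulus = 3.4,
                          head_width = 4, interface_width = 6,
                          sigma_star = 0, boundary_layer = 10) {
  stopifnot(inner_radius > 0, outer_radius > inner_radius,
            rest_thickness > 0, areal_modulus > 0, sigma_star >= 0,
            head_width > 0, interface_width > 0,
            2 * (head_width + interface_width) < rest_thickness)
  structure(list(inner_radius = inner_radius, outer_radius = outer_radius,
                 rest_thickness = rest_thickness,
                 areal_modulus = areal_modulus,
                 head_width = head_width, interface_width = interface_width,
                 sigma_star = sigma_star, boundary_layer = boundary_layer),
            class = "bilayer_patch")
}

#' Areal stretch under tension
#'
#' Linear areal elasticity of the bilayer: `stretch = 1 + sigma* / K_A*`.
#'
#' @param patch a `bilayer_patch`.
#' @param sigma_star nondimensional tension (defaults to the patch value).
#' @return areal stretch (>= 1).
#' @export
areal_stretch <- function(patch, sigma_star = patch$sigma_star) {
  stopifnot(sigma_star >= 0)
  1 + sigma_star / patch$areal_modulus
}

#' Thinning response of the bilayer
#'
#' Volume-conserving thinning: the far-field thickness is `h0 / stretch`,
#' with a smooth exponential boundary layer at the protein inner radius where
#' the hydrophobic span of the protein holds the membrane closer to its rest
#' thickness. Returns the percent thinning of the far field,
#' `100 * (1 - h/h0)`.
#'
#' @param patch a `bilayer_patch`.
#' @param stretch areal stretch (>= 1; compression is out of scope).
#' @return list with `h_far` (far-field thickness, Angstrom),
#'   `thinning_percent`, and `thickness`, a vectorized function of radius r
#'   giving h(r).
#' @export
thinning_response <- function(patch, stretch) {
  if (stretch < 1) stop("areal stretch < 1: membrane compression is out of scope")
  h0 <- patch$rest_thickness
  h_far <- h0 / stretch
  r_in <- patch$inner_radius; lam <- patch$boundary_layer
  thickness <- function(r) {
    r <- pmax(r, r_in)
    h_far + (h0 - h_far) * exp(-(r - r_in) / lam)
  }
  list(h_far = h_far,
       thinning_percent = 100 * (1 - h_far / h0),
       thickness = thickness)
}

#' Mean-field lateral pressure profile
#'
#' Piecewise-constant depth profile of lateral stress across the bilayer:
#' positive (repulsive) pressure in the headgroup bands, a small positive
#' pressure in the acyl tail core, and negative (tension-carrying) pressure
#' in the two head/tail interfacial bands. Amplitudes scale affinely with
#' the applied nondimensional tension and satisfy the zeroth-moment
#' constraint: the integral of the profile over depth (in units of the rest
#' thickness) equals `-sigma*`, so the profile carries exactly the applied
#' tension; at `sigma* = 0` the profile integrates to zero.
#'
#' @param patch a `bilayer_patch` (band geometry; its current thickness is
#'   set by `thickness`).
#' @param sigma_star applied nondimensional tension.
#' @param thickness current bilayer thickness (Angstrom); defaults to rest.
#' @param head_frac fraction of sigma* appearing as extra repulsive head
#'   pressure (compensated at the interfaces).
#' @param tail_frac same for the tail core band.
#' @param split_bottom fraction of the interfacial tension carried by the
#'   cytoplasmic (bottom) interface band.
#' @return object of class `pressure_profile` with a `bands` data.frame
#'   (`name`, `zlo`, `zhi`, `pressure`), the generating parameters, and the
#'   reference thickness used for moment normalization.
#' @export
build_pressure_profile <- function(patch, sigma_star = patch$sigma_star,
                                   thickness = patch$rest_thickness,
                                   head_frac = 0.15, tail_frac = 0.05,
                                   split_bottom = 0.5) {
  stopifnot(sigma_star >= 0, thickness > 0,
            split_bottom >= 0, split_bottom <= 1)
  wh <- patch$head_width; wi <- patch$interface_width
  h <- thickness
  if (2 * (wh + wi) >= h)
    stop("infeasible band geometry: head and interface bands exceed thickness")
  h0 <- patch$rest_thickness
  zs <- c(-h / 2, -h / 2 + wh, -h / 2 + wh + wi,
          h / 2 - wh - wi, h / 2 - wh, h / 2)
  wt <- zs[4L] - zs[3L]                       # tail core width
  # sigma*-proportional amplitudes (dimensionless stress, z-moment in units
  # of the rest thickness h0)
  p_head <- sigma_star * head_frac * h0 / (2 * wh)
  p_tail <- sigma_star * tail_frac * h0 / wt
  tension_total <- sigma_star * (1 + head_frac + tail_frac) * h0
  p_ib <- -tension_total * split_bottom / wi
  p_it <- -tension_total * (1 - split_bottom) / wi
  bands <- data.frame(
    name = c("head_bottom", "interface_bottom", "tail", "interface_top",
             "head_top"),
    zlo = zs[1:5], zhi = zs[2:6],
    pressure = c(p_head, p_ib, p_tail, p_it, p_head),
    stringsAsFactors = FALSE)
  structure(list(bands = bands, sigma_star = sigma_star,
                 thickness = h, h0 = h0,
                 head_frac = head_frac, tail_frac = tail_frac,
                 split_bottom = split_bottom),
            class = "pressure_profile")
}

#' Evaluate a lateral pressure profile
#'
#' @param profile a `pressure_profile`.
#' @param z depth(s) in Angstrom (midplane at 0, periplasmic side positive).
#' @param smooth band-edge smoothing half-width in Angstrom. 0 (default)
#'   evaluates the exact piecewise-constant profile; a positive value blends
#'   band edges with a C1 smoothstep of that half-width (used by the solver,
#'   which needs differentiable loads). The smoothing is symmetric about
#'   each edge, so the zeroth moment is preserved.
#' @return dimensionless lateral pressure at each z (0 outside the membrane).
#' @export
pressure_at <- function(profile, z, smooth = 0) {
  b <- profile$bands
  if (smooth <= 0) {
    out <- numeric(length(z))
    for (k in seq_len(nrow(b))) {
      inb <- z >= b$zlo[k] & z < b$zhi[k]
      out[inb] <- b$pressure[k]
    }
    out[z == b$zhi[nrow(b)]] <- b$pressure[nrow(b)]
    return(out)
  }
  # sum of smoothed steps at each band edge; step height = pressure jump
  edges <- c(b$zlo[1L], b$zhi)
  levels <- c(0, b$pressure, 0)
  out <- numeric(length(z))
  sstep <- function(t) {           # C1 smoothstep on [0,1]
    t <- pmin(pmax(t, 0), 1)
    t * t * (3 - 2 * t)
  }
  for (k in seq_along(edges)) {
    jump <- levels[k + 1L] - levels[k]
    out <- out + jump * sstep((z - (edges[k] - smooth)) / (2 * smooth))
  }
  out
}

#' Zeroth moment of a pressure profile
#'
#' Integral of the profile over depth in units of the rest thickness;
#' equals `-sigma*` by construction.
#'
#' @param profile a `pressure_profile`.
#' @return dimensionless moment.
#' @export
profile_moment <- function(profile) {
  b <- profile$bands
  sum(b$pressure * (b$zhi - b$zlo)) / profile$h0
}

#' Distributed membrane load on rod nodes
#'
#' Converts the lateral pressure profile into nodal forces on a discretized
#' rod: each node whose depth lies within the membrane span receives the band
#' pressure at its depth, acting on its tributary surface area
#' (tributary length x rod diameter) along the local inward membrane normal
#' (the direction from the membrane toward the fivefold axis), so that
#' tension-carrying (negative) bands pull the rod radially outward. Nodes
#' outside the membrane span receive zero load.
#'
#' @param profile a `pressure_profile`.
#' @param positions n x 3 matrix of current node positions (Angstrom).
#' @param tributary_area numeric vector of per-node surface areas
#'   (Angstrom^2).
#' @param smooth band-edge smoothing passed to [pressure_at()].
#' @return n x 3 matrix of nodal forces (dimensionless, units of E x A^2).
#' @export
membrane_load_on_rod <- function(profile, positions, tributary_area,
                                 smooth = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be n x 3")
  if (anyNA(positions)) stop("untagged node: positions contain NA")
  n <- nrow(positions)
  if (length(tributary_area) == 1L) tributary_area <- rep(tributary_area, n)
  stopifnot(length(tributary_area) == n)
  p <- pressure_at(profile, positions[, 3L], smooth = smooth)
  F <- matrix(0, n, 3L)
  r <- sqrt(positions[, 1L]^2 + positions[, 2L]^2)
  ok <- p != 0 & r > 1e-9
  # inward normal is -rhat; force on the rod = p * area * (-rhat)
  F[ok, 1L] <- -p[ok] * tributary_area[ok] * positions[ok, 1L] / r[ok]
  F[ok, 2L] <- -p[ok] * tributary_area[ok] * positions[ok, 2L] / r[ok]
  F
}
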