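# Quasi-static nonlinear solver for the rod/hinge/spring channel system
# under membrane pressure-profile loads and van der Waals contact tractions.
# Loading is nondimensional (sigma* = membrane stress / protein modulus E);
# the solution is advanced by incremental continuation with Newton
# iteration at each load level. Deterministic: no randomness anywhere.

#' Solver configuration
#'
#' Numerical settings and the frozen default calibration of the continuum
#' model (rod stiffness ratios, loop-spring law, membrane coupling
#' constants). All stiffnesses are dimensionless ratios to the protein
#' Young's modulus E.
#'
#' @param sigma_max final nondimensional membrane tension of the ramp.
#' @param n_increments number of equal load increments from 0 to
#'   `sigma_max`.
#' @param nodes_per_helix mesh density: nodes per rod (>= 4).
#' @param tol Newton convergence tolerance on the residual norm (relative
#'   to the external load norm).
#' @param max_iter maximum Newton iterations per increment.
#' @param max_halvings adaptive increment halvings before giving up.
#' @param stiffness_ratio named vector of rod modulus ratios for NTERM,
#'   TM1, TM2 (default all 1: uniform protein modulus).
#' @param loop_table two-column matrix (extension A, force) for the
#'   nonlinear loop wires; default a hardening law.
#' @param k_tie translational penalty stiffness of hinge junctions.
#' @param k_hinge_lock rotational stiffness locking the non-free hinge
#'   rotations.
#' @param k_linker axial stiffness of the glycine-linker connector used for
#'   +nG variants.
#' @param k_vert vertical membrane-drag stiffness per unit rod surface area
#'   of the TM helices (couples rod depth to the thinning bilayer, the
#'   hydrophobic-matching squeeze that converts thinning into tilt).
#' @param k_vert_nterm same for the N-terminal helix; weak by default so
#'   the interfacial helix can reorient out of the plane while gating.
#' @param k_lat lateral interface-embedding stiffness per unit area of the
#'   amphipathic N-terminal helix: its nodes are elastically anchored to
#'   their material positions in the stretching membrane plane (advected
#'   outward by the areal stretch), so the interfacial helix follows the
#'   trajectory of its surrounding lipids.
#' @param k_lat_tm same lateral embedding for the TM helices (acyl-chain
#'   caging of the transmembrane surfaces); much weaker than the N-term
#'   interface embedding, acts in addition to the van der Waals rim
#'   adhesion.
#' @param k_rim_bot,k_rim_top radial stiffnesses of the bilayer inner-rim
#'   rings at the cytoplasmic and periplasmic surfaces. The inner rim is a
#'   cone interpolating between the two rings; a compliant cytoplasmic ring
#'   and a stiff periplasmic ring let the hole open as a funnel (feet flare
#'   outward while the helix tops stay put), which is what converts the
#'   interfacial pull into helix tilt.
#' @param nterm_advect fraction of the near-rim lipid displacement felt by
#'   the N-terminal anchors (the interfacial helix sits between the rim
#'   foot and the pore mouth, where the lipid flow has partly decayed).
#' @param thinning_gamma exponent of the local thinning felt at the
#'   protein boundary relative to the far field: the vertical-drag anchors
#'   scale with `(h/h0)^thinning_gamma`. Values above 1 represent the
#'   stress concentration at the hole edge (the bilayer next to the
#'   protein thins more than the far field).
#' @param k_reg grounding regularization stiffness on all dofs.
#' @param head_frac,tail_frac,split_bottom lateral-pressure-profile shape
#'   parameters (see [build_pressure_profile()]).
#' @param smooth band-edge smoothing (A) used inside the solver.
#' @param step_max largest per-dof Newton step (A or rad) before clamping.
#' @param stab0 initial automatic-stabilization (pseudo-transient) damping
#'   factor; decays to zero as the iteration converges.
#' @param symmetry if TRUE (default), exploit the exact C5 symmetry of the
#'   pentamer: only one subunit is discretized and the other four are its
#'   72-degree rotated images (the subunits interact only through the
#'   axisymmetric membrane, so the reduction is exact for symmetric
#'   models). Set FALSE to solve all five subunits independently.
#' @param seed unused by the solver (it is deterministic); kept so run
#'   configurations can carry a seed for fixture generation.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(sigma_max = 0.6, n_increments = 30,
                          nodes_per_helix = 8, tol = 1e-6, max_iter = 120,
                          max_halvings = 5,
                          stiffness_ratio = c(NTERM = 500, TM1 = 500,
                                              TM2 = 500),
                          loop_table = default_loop_table(),
                          k_tie = 1000, k_hinge_lock = 2000, k_linker = 0.2,
                          k_vert = 1.2, k_vert_nterm = 0.3,
                          k_lat = 1.3, k_lat_tm = 0.06,
                          k_rim_bot = 150, k_rim_top = 2000,
                          nterm_advect = 0.33, thinning_gamma = 2.5,
                          k_reg = 1e-2,
                          head_frac = 0.15, tail_frac = 0.05,
                          split_bottom = 0.95, smooth = 1, step_max = 1.5,
                          stab0 = 0.05, symmetry = TRUE, seed = NULL) {
  stopifnot(sigma_max >= 0, n_increments >= 1, nodes_per_helix >= 4,
            tol > 0, max_iter >= 1, step_max > 0)
  structure(list(sigma_max = sigma_max, n_increments = n_increments,
                 nodes_per_helix = as.integer(nodes_per_helix), tol = tol,
                 max_iter = max_iter, max_halvings = max_halvings,
                 stiffness_ratio = stiffness_ratio, loop_table = loop_table,
                 k_tie = k_tie, k_hinge_lock = k_hinge_lock,
                 k_linker = k_linker, k_vert = k_vert,
                 k_vert_nterm = k_vert_nterm, k_lat = k_lat,
                 k_lat_tm = k_lat_tm, k_rim_bot = k_rim_bot,
                 k_rim_top = k_rim_top, nterm_advect = nterm_advect,
                 thinning_gamma = thinning_gamma,
                 k_reg = k_reg, head_frac = head_frac, tail_frac = tail_frac,
                 split_bottom = split_bottom, smooth = smooth,
                 step_max = step_max, stab0 = stab0, symmetry = symmetry,
                 seed = seed),
            class = "solver_config")
}

#' Default loop-wire force-extension law
#'
#' Hardening force-extension table for the periplasmic loops modelled as
#' nonlinear wires: soft at small extension, stiffening at large extension.
#' Passes through (0, 0) and is monotone.
#'
#' @param k1 linear coefficient (force per A of extension).
#' @param k3 cubic hardening coefficient.
#' @param ext_max table range (A).
#' @return two-column matrix (extension, force).
#' @export
default_loop_table <- function(k1 = 0.2, k3 = 0.03, ext_max = 30) {
  ext <- seq(0, ext_max, by = 0.5)
  cbind(extension = ext, force = k1 * ext + k3 * ext^3)
}

node_dofs <- function(i) (6L * (i - 1L) + 1L):(6L * i)

# Merge the translational dofs of tied hinge pairs (the G14 junction pins
# the N-term C-end to the TM1 N-end exactly) and build the full -> reduced
# dof map used by the assembly.
finalize_dof_map <- function(sys) {
  dmap <- seq_len(sys$n_dof)
  for (hg in sys$hinges) {
    if (isTRUE(hg$tie)) {
      da <- node_dofs(hg$node_a)[1:3]
      db <- node_dofs(hg$node_b)[1:3]
      lo <- pmin(da, db); hi <- pmax(da, db)
      dmap[hi] <- dmap[lo]
    }
  }
  dmap <- match(dmap, sort(unique(dmap)))
  sys$dmap <- dmap
  sys$n_red <- max(dmap)
  sys
}

#' Assemble the discrete channel system
#'
#' Discretizes every helix rod into beam elements, attaches the hinge
#' connectors (or flexible glycine-linker connectors for +nG variants), the
#' loop wires and the membrane coupling (pressure-profile loads, vertical
#' drag, van der Waals rim adhesion). Helix-helix elastic interactions are
#' deliberately absent: the rods communicate only through the membrane and
#' the explicit connectors.
#'
#' @param model a `channel_model`.
#' @param patch a `bilayer_patch`.
#' @param law a `vdw_law`.
#' @param config a `solver_config`.
#' @return object of class `channel_system`.
#' @export
assemble_system <- function(model, patch = bilayer_patch(), law = vdw_law(),
                            config = solver_config()) {
  npH <- config$nodes_per_helix
  rod_radius <- model$helices[[1L]]$rod_diameter / 2

  full_model <- model
  symmetric <- isTRUE(config$symmetry) && model$symmetry_order == 5L
  if (symmetric) {
    keep <- vapply(model$helices, function(s) s$subunit_index == 0L, TRUE)
    model$helices <- model$helices[keep]
    model$hinges <- Filter(function(h) h$subunit == 0L, model$hinges)
    model$loops <- Filter(function(l) l$subunit == 0L, model$loops)
  }

  X0 <- NULL
  node_rod <- integer(0); node_class <- character(0)
  node_sub <- integer(0); trib <- numeric(0)
  rods <- list()
  elements <- list()
  for (ri in seq_along(model$helices)) {
    seg <- model$helices[[ri]]
    ends <- segment_ends(seg)
    ts <- seq(0, 1, length.out = npH)
    pts <- outer(1 - ts, ends$n) + outer(ts, ends$c)
    ids <- nrow0 <- if (is.null(X0)) 0L else nrow(X0)
    ids <- nrow0 + seq_len(npH)
    X0 <- rbind(X0, pts)
    node_rod <- c(node_rod, rep(ri, npH))
    node_class <- c(node_class, rep(seg$name, npH))
    node_sub <- c(node_sub, rep(seg$subunit_index, npH))
    dl <- seg$length / (npH - 1L)
    tr <- rep(dl, npH); tr[c(1L, npH)] <- dl / 2
    trib <- c(trib, tr)
    rods[[ri]] <- ids
    sec <- rod_section(seg$rod_diameter,
                       config$stiffness_ratio[[seg$name]])
    E0 <- element_triad(seg$axis_direction)
    for (k in seq_len(npH - 1L)) {
      el <- list(i = ids[k], j = ids[k + 1L], L0 = dl, E0 = E0,
                 EA = sec$EA, EI = sec$EI, GJ = sec$GJ,
                 A = sec$A, I = sec$I, W = sec$W,
                 class = seg$name, subunit = seg$subunit_index, rod = ri)
      el$Kl <- local_stiffness(el)
      el$X0i <- pts[k, ]; el$X0j <- pts[k + 1L, ]
      el$dofs <- c(node_dofs(ids[k]), node_dofs(ids[k + 1L]))
      elements[[length(elements) + 1L]] <- el
    }
  }
  n_nodes <- nrow(X0)

  rod_index <- function(name, subunit) {
    for (ri in seq_along(model$helices)) {
      s <- model$helices[[ri]]
      if (s$name == name && s$subunit_index == subunit) return(ri)
    }
    stop("no ", name, " rod in subunit ", subunit)
  }

  hinges <- list(); springs <- list()
  for (hg in model$hinges) {
    na <- rods[[rod_index("NTERM", hg$subunit)]][npH]   # N-term C-end
    nb <- rods[[rod_index("TM1", hg$subunit)]][1L]      # TM1 N-end
    if (hg$linker_extension == 0L) {
      hinges[[length(hinges) + 1L]] <- list(
        node_a = na, node_b = nb, axis = hg$free_axis,
        k_lock = config$k_hinge_lock,
        k_free = hg$rotational_stiffness * config$k_hinge_lock,
        tie = TRUE)
    } else {
      # +nG variant: flexible connector of rest length n x 1.5 A with no
      # rotational coupling (near-zero bending stiffness)
      rl <- hg$linker_extension * 1.5
      tb <- cbind(extension = c(0, 25, 50),
                  force = c(0, 25, 50) * config$k_linker)
      springs[[length(springs) + 1L]] <- list(
        i = na, j = nb, rest_len = rl, table = tb,
        fun = stats::splinefun(tb[, 1L], tb[, 2L], method = "monoH.FC"),
        tension_only = TRUE, type = "linker", subunit = hg$subunit)
    }
  }
  for (lp in model$loops) {
    ia <- rods[[rod_index(lp$from[1L], lp$subunit)]][npH]
    ib <- rods[[rod_index(lp$to[1L], lp$subunit)]][1L]
    rl <- vnorm(X0[ia, ] - X0[ib, ])
    # loops carry tension and (weak) compression: odd-extend the table
    tb <- config$loop_table
    tb <- rbind(cbind(-rev(tb[-1L, 1L]), -rev(tb[-1L, 2L])), tb)
    springs[[length(springs) + 1L]] <- list(
      i = ia, j = ib, rest_len = rl, table = tb,
      fun = stats::splinefun(tb[, 1L], tb[, 2L], method = "monoH.FC"),
      tension_only = FALSE, type = "loop", subunit = lp$subunit)
  }

  # Per-node coupling weights are tributary-overlap fractions (the share
  # of a node's tributary rod segment inside the relevant region), so the
  # effective coupled areas converge smoothly under mesh refinement
  # instead of jumping by half a node spacing.
  #
  # - w_exposed: lipid-exposed surface share. The interfacial N-term and
  #   the lipid-facing TM2 (within the membrane span) are exposed; of TM1
  #   only the upper, periplasmic-funnel half (z >= 0) is -- its lower
  #   half lines the pore and is shielded, so without the N-terminal
  #   antenna the channel foot collects almost no interfacial tension
  #   (the origin of the deletion phenotype in this model).
  # - w_anchor: membrane-embedding share of the N-term, restricted to its
  #   distal (most buried, consensus-motif) 3/8 near the G14 junction;
  #   the proximal end is aqueous-exposed and unanchored, so the load it
  #   carries is reacted through the helix, concentrating bending there.
  # - w_upper: TM share above the midplane, where the vertical
  #   (hydrophobic-matching) drag acts.
  h0 <- patch$rest_thickness
  w_exposed <- numeric(n_nodes)
  w_anchor <- numeric(n_nodes)
  w_upper <- numeric(n_nodes)
  for (ri in seq_along(model$helices)) {
    seg <- model$helices[[ri]]
    ids <- rods[[ri]]
    s <- seq(0, seg$length, length.out = npH)
    dl <- seg$length / (npH - 1L)
    lo <- pmax(s - dl / 2, 0); hi <- pmin(s + dl / 2, seg$length)
    zn <- X0[ids[1L], 3L]; zc <- X0[ids[npH], 3L]
    z_of_s <- function(sv) zn + (zc - zn) * sv / seg$length
    # overlap fraction of [lo, hi] with { s : z(s) in [z1, z2] }
    frac_z <- function(z1, z2) {
      if (abs(zc - zn) < 1e-12) {
        return(as.numeric(zn >= z1 & zn <= z2))
      }
      s1 <- (z1 - zn) * seg$length / (zc - zn)
      s2 <- (z2 - zn) * seg$length / (zc - zn)
      a <- pmin(s1, s2); b <- pmax(s1, s2)
      pmin(pmax((pmin(hi, b) - pmax(lo, a)) / (hi - lo), 0), 1)
    }
    if (seg$name == "NTERM") {
      w_exposed[ids] <- 1
      # distal 3/8 of the arclength (s measured from the free N-end)
      a_star <- 5 / 8 * seg$length
      w_anchor[ids] <- pmin(pmax((hi - pmax(lo, a_star)) / (hi - lo), 0), 1)
    } else if (seg$name == "TM2") {
      w_exposed[ids] <- frac_z(-h0 / 2, h0 / 2)
      w_upper[ids] <- frac_z(0, 1e9)     # above midplane, incl. overhang
      w_anchor[ids] <- 1
    } else {
      w_exposed[ids] <- frac_z(0, h0 / 2)
      w_upper[ids] <- frac_z(0, 1e9)
      w_anchor[ids] <- 1
    }
  }
  # van der Waals slave set: exposed TM surfaces
  slave <- which(w_exposed > 0 & node_class != "NTERM")
  r0 <- sqrt(X0[slave, 1L]^2 + X0[slave, 2L]^2)
  rim_R0 <- max(r0 + rod_radius) + law$d0
  g0 <- rim_R0 - r0 - rod_radius           # rest gaps (adhesion equilibrium)

  sys <- structure(list(model = full_model, patch = patch, law = law,
                 config = config,
                 X0 = X0, n_nodes = n_nodes, n_dof = 6L * n_nodes + 2L,
                 node_rod = node_rod, node_class = node_class,
                 node_subunit = node_sub, trib_len = trib,
                 rod_radius = rod_radius,
                 rods = rods, elements = elements, springs = springs,
                 hinges = hinges,
                 w_exposed = w_exposed, w_anchor = w_anchor,
                 w_upper = w_upper,
                 depth_frac = pmin(pmax((X0[, 3L] + h0 / 2) / h0, 0), 1),
                 slave = slave, slave_g0 = g0, rim_R0 = rim_R0,
                 symmetric = symmetric,
                 rim_mult = if (symmetric) 5 else 1,
                 fixed = integer(0), point_loads = NULL,
                 has_membrane = TRUE),
            class = "channel_system")
  finalize_dof_map(sys)
}

#' @export
print.channel_system <- function(x, ...) {
  cat(sprintf("<channel_system> %d nodes, %d beam elements, %d springs, %d hinges, %d dofs\n",
              x$n_nodes, length(x$elements), length(x$springs),
              length(x$hinges), x$n_dof))
  invisible(x)
}

#' Node positions of one subunit of a solved state
#'
#' Returns the current positions of the nodes of a given helix in a given
#' subunit. For symmetry-reduced systems the positions of subunits 1-4 are
#' the exact 72-degree rotated images of subunit 0.
#'
#' @param sys a `channel_system`.
#' @param state a `system_state`.
#' @param name helix class (`"NTERM"`, `"TM1"`, `"TM2"`).
#' @param subunit subunit index 0-4.
#' @return matrix of node positions (nodes_per_helix x 3).
#' @export
helix_node_positions <- function(sys, state, name, subunit = 0) {
  if (isTRUE(sys$symmetric)) {
    sel <- which(sys$node_class == name & sys$node_subunit == 0L)
    if (length(sel) == 0L) stop("no ", name, " nodes in the system")
    pts <- state$positions[sel, , drop = FALSE]
    if (subunit != 0) pts <- t(rotation_z(72 * subunit) %*% t(pts))
    return(pts)
  }
  sel <- which(sys$node_class == name & sys$node_subunit == subunit)
  if (length(sel) == 0L) stop("no ", name, " nodes in subunit ", subunit)
  state$positions[sel, , drop = FALSE]
}

# current nodal positions from the (reduced) dof vector
node_positions <- function(sys, d) {
  df <- d[sys$dmap]
  u <- matrix(df[seq_len(6L * sys$n_nodes)], ncol = 6L, byrow = TRUE)[, 1:3]
  sys$X0 + u
}

node_rotations <- function(sys, d) {
  df <- d[sys$dmap]
  matrix(df[seq_len(6L * sys$n_nodes)], ncol = 6L, byrow = TRUE)[, 4:6]
}

# scalar derivative of the vdw traction (vectorized finite difference)
vdw_traction_deriv <- function(D, law, h = 1e-6) {
  (vdw_traction(D + h, law) - vdw_traction(pmax(D - h, 1e-9), law)) / (2 * h)
}

# Assemble residual (internal - external) and optionally the tangent.
# radial_dirs: n x 2 matrix of frozen radial load directions (incremental
# follower loads: directions are updated once per load increment from the
# last converged geometry, mirroring the incremental contact contract of
# the surface-interaction subroutine). NULL recomputes them from the
# current geometry.
residual_system <- function(sys, d, sigma, need_K = TRUE,
                            radial_dirs = NULL) {
  cfg <- sys$config
  dm <- sys$dmap
  nr <- sys$n_red
  R <- numeric(nr)
  K <- if (need_K) matrix(0, nr, nr) else NULL
  x <- node_positions(sys, d)
  df <- d[dm]                      # full-space dof values

  # --- beam elements
  for (el in sys$elements) {
    idx <- dm[el$dofs]
    de <- df[el$dofs]
    if (need_K) {
      out <- beam_element_tangent(de, el$X0i, el$X0j, el)
      R[idx] <- R[idx] + out$F
      K[idx, idx] <- K[idx, idx] + out$K
    } else {
      R[idx] <- R[idx] +
        beam_internal_force(de, el$X0i, el$X0j, el)$F
    }
  }

  # --- springs (loops, +nG linkers)
  for (sp in sys$springs) {
    out <- spring_response(x[sp$i, ], x[sp$j, ], sp$rest_len, sp$table,
                           sp$tension_only, sp$fun)
    idx <- dm[c(node_dofs(sp$i)[1:3], node_dofs(sp$j)[1:3])]
    R[idx] <- R[idx] + out$F
    if (need_K) K[idx, idx] <- K[idx, idx] + out$K
  }

  # --- hinge connectors (translations are tied exactly via the dof map;
  #     only the rotational coupling is assembled)
  for (hg in sys$hinges) {
    ta <- node_dofs(hg$node_a)[4:6]; tb <- node_dofs(hg$node_b)[4:6]
    hr <- hinge_response(df[ta], df[tb], hg$axis, hg$k_lock, hg$k_free)
    idx <- dm[c(ta, tb)]
    R[idx] <- R[idx] + hr$F
    if (need_K) K[idx, idx] <- K[idx, idx] + hr$K
  }

  # --- grounding regularization (on reduced dofs; rim excluded)
  dk <- seq_len(nr - 1L)
  R[dk] <- R[dk] + cfg$k_reg * d[dk]
  if (need_K) K[cbind(dk, dk)] <- K[cbind(dk, dk)] + cfg$k_reg

  # --- constant point loads (benchmark systems)
  if (!is.null(sys$point_loads)) {
    idx <- dm[sys$point_loads$dofs]
    R[idx] <- R[idx] - sigma * sys$point_loads$values
  }

  ext_norm <- 0
  if (isTRUE(sys$has_membrane)) {
    patch <- sys$patch; law <- sys$law
    stretch <- areal_stretch(patch, sigma)
    h <- patch$rest_thickness / stretch
    prof <- build_pressure_profile(patch, sigma, thickness = h,
                                   head_frac = cfg$head_frac,
                                   tail_frac = cfg$tail_frac,
                                   split_bottom = cfg$split_bottom)
    area <- sys$trib_len * (2 * sys$rod_radius)
    rb <- nr - 1L                      # cytoplasmic rim-ring dof
    rt <- nr                           # periplasmic rim-ring dof
    nn <- sys$n_nodes
    if (is.null(radial_dirs)) {
      rr <- sqrt(x[, 1L]^2 + x[, 2L]^2)
      radial_dirs <- cbind(x[, 1L] / pmax(rr, 1e-9),
                           x[, 2L] / pmax(rr, 1e-9))
    }

    # pressure-profile loads along the frozen radial directions: tension
    # bands (p < 0) pull the rods outward
    p <- pressure_at(prof, x[, 3L], smooth = cfg$smooth)
    # the amphipathic N-term partitions into the cytoplasmic interface by
    # construction: it always carries the interfacial-band tension, rather
    # than gaining or losing it through depth bookkeeping as the band
    # migrates with thinning
    nt_nodes <- sys$node_class == "NTERM"
    if (any(nt_nodes)) {
      pib <- prof$bands$pressure[prof$bands$name == "interface_bottom"]
      p[nt_nodes] <- pib
    }
    fmag <- -p * area * sys$w_exposed
    hsm <- 1e-4
    dp <- if (need_K)
      (pressure_at(prof, x[, 3L] + hsm, smooth = cfg$smooth) -
         pressure_at(prof, x[, 3L] - hsm, smooth = cfg$smooth)) / (2 * hsm)
    else numeric(nn)
    dp <- dp * sys$w_exposed
    dp[sys$node_class == "NTERM"] <- 0
    # vertical membrane drag: nodes follow the thinning bilayer
    # the drag acts on the N-term (interfacial positioning) and on the
    # upper halves of the TM rods (periplasmic matching); the depth of the
    # cytoplasmic ends is set by the structure itself (the N-term handle at
    # the interface), which is what lets the TM rods rotate rather than
    # translate when their feet are pulled outward
    z_anchor <- sys$X0[, 3L] *
      (h / patch$rest_thickness)^cfg$thinning_gamma
    kv <- ifelse(sys$node_class == "NTERM",
                 cfg$k_vert_nterm * sys$w_anchor,
                 cfg$k_vert * sys$w_upper) * area
    # lateral membrane embedding: nodes are anchored to their surrounding
    # lipid material, which near the protein translates radially with the
    # bilayer inner rim (anchor = rest position + rim displacement along
    # the rest radial direction); reactions act back on the rim ring
    klat <- ifelse(sys$node_class == "NTERM",
                   cfg$k_lat * sys$w_anchor, cfg$k_lat_tm) * area
    # rim cone: per-node radial displacement of the inner membrane surface
    # interpolated between the two rim rings by depth
    xiw <- sys$depth_frac
    dRim <- (1 - xiw) * d[rb] + xiw * d[rt]
    # anchor advection fraction: TM surfaces ride the rim cone fully, the
    # N-term rides a damped fraction of it
    af <- ifelse(sys$node_class == "NTERM", cfg$nterm_advect, 1)

    # van der Waals rim adhesion (slave nodes vs rim ring dof); gaps are
    # measured along the frozen radial directions
    Svec <- numeric(nn); SpA <- numeric(nn)
    sl <- sys$slave
    rs <- x[sl, 1L] * radial_dirs[sl, 1L] + x[sl, 2L] * radial_dirs[sl, 2L]
    gap <- (sys$rim_R0 + dRim[sl]) - rs - sys$rod_radius
    Deff <- pmax(law$d0 + (gap - sys$slave_g0), 0.05 * law$d0)
    Svec[sl] <- vdw_traction(Deff, law)
    if (need_K) {
      Sp <- vdw_traction_deriv(Deff, law)
      Sp[Deff <= 0.05 * law$d0 + 1e-12] <- 0
      SpA[sl] <- Sp * area[sl] * sys$w_exposed[sl]
    }
    fS <- Svec * area * sys$w_exposed

    for (i in seq_len(nn)) {
      bix <- dm[6L * (i - 1L) + 1L]
      biy <- dm[6L * (i - 1L) + 2L]
      biz <- dm[6L * (i - 1L) + 3L]
      e1 <- radial_dirs[i, 1L]; e2 <- radial_dirs[i, 2L]
      ftot <- fmag[i] + fS[i]
      R[bix] <- R[bix] - ftot * e1
      R[biy] <- R[biy] - ftot * e2
      R[biz] <- R[biz] + kv[i] * (x[i, 3L] - z_anchor[i])
      if (klat[i] > 0) {
        r0i <- sqrt(sys$X0[i, 1L]^2 + sys$X0[i, 2L]^2)
        rh01 <- sys$X0[i, 1L] / max(r0i, 1e-9)
        rh02 <- sys$X0[i, 2L] / max(r0i, 1e-9)
        ax <- sys$X0[i, 1L] + af[i] * dRim[i] * rh01
        ay <- sys$X0[i, 2L] + af[i] * dRim[i] * rh02
        fx <- klat[i] * (x[i, 1L] - ax)
        fy <- klat[i] * (x[i, 2L] - ay)
        R[bix] <- R[bix] + fx
        R[biy] <- R[biy] + fy
        # reaction of the embedding on the rim rings
        fr <- af[i] * (fx * rh01 + fy * rh02)
        R[rb] <- R[rb] - sys$rim_mult * (1 - xiw[i]) * fr
        R[rt] <- R[rt] - sys$rim_mult * xiw[i] * fr
      }
      if (need_K) {
        K[biz, biz] <- K[biz, biz] + kv[i]
        if (klat[i] > 0) {
          K[bix, bix] <- K[bix, bix] + klat[i]
          K[biy, biy] <- K[biy, biy] + klat[i]
          for (rr2 in 1:2) {
            rd <- if (rr2 == 1L) rb else rt
            wgt <- (if (rr2 == 1L) 1 - xiw[i] else xiw[i]) * af[i]
            K[bix, rd] <- K[bix, rd] - wgt * klat[i] * rh01
            K[biy, rd] <- K[biy, rd] - wgt * klat[i] * rh02
            K[rd, bix] <- K[rd, bix] - sys$rim_mult * wgt * klat[i] * rh01
            K[rd, biy] <- K[rd, biy] - sys$rim_mult * wgt * klat[i] * rh02
          }
          wsq <- klat[i] * (rh01^2 + rh02^2) * sys$rim_mult * af[i]^2
          K[rb, rb] <- K[rb, rb] + wsq * (1 - xiw[i])^2
          K[rb, rt] <- K[rb, rt] + wsq * (1 - xiw[i]) * xiw[i]
          K[rt, rb] <- K[rt, rb] + wsq * (1 - xiw[i]) * xiw[i]
          K[rt, rt] <- K[rt, rt] + wsq * xiw[i]^2
        }
        if (dp[i] != 0) {
          K[bix, biz] <- K[bix, biz] + dp[i] * area[i] * e1
          K[biy, biz] <- K[biy, biz] + dp[i] * area[i] * e2
        }
        if (SpA[i] != 0) {
          K[bix, bix] <- K[bix, bix] + SpA[i] * e1 * e1
          K[bix, biy] <- K[bix, biy] + SpA[i] * e1 * e2
          K[biy, bix] <- K[biy, bix] + SpA[i] * e2 * e1
          K[biy, biy] <- K[biy, biy] + SpA[i] * e2 * e2
          for (rr2 in 1:2) {
            rd <- if (rr2 == 1L) rb else rt
            wgt <- if (rr2 == 1L) 1 - xiw[i] else xiw[i]
            K[bix, rd] <- K[bix, rd] - wgt * SpA[i] * e1
            K[biy, rd] <- K[biy, rd] - wgt * SpA[i] * e2
            K[rd, bix] <- K[rd, bix] - sys$rim_mult * wgt * SpA[i] * e1
            K[rd, biy] <- K[rd, biy] - sys$rim_mult * wgt * SpA[i] * e2
          }
          wsq <- SpA[i] * sys$rim_mult
          K[rb, rb] <- K[rb, rb] + wsq * (1 - xiw[i])^2
          K[rb, rt] <- K[rb, rt] + wsq * (1 - xiw[i]) * xiw[i]
          K[rt, rb] <- K[rt, rb] + wsq * (1 - xiw[i]) * xiw[i]
          K[rt, rt] <- K[rt, rt] + wsq * xiw[i]^2
        }
      }
    }
    ext_norm <- sqrt(sum(fmag^2)) + sqrt(sum(fS^2))
    # rim rings: elastic rings about the tension-advected free radius,
    # loaded by the depth-weighted reactions of the slave tractions
    # (Newton's third law); under C5 reduction one subunit stands for five
    R_free_disp <- sys$rim_R0 * (sqrt(stretch) - 1)
    R[rb] <- R[rb] + cfg$k_rim_bot * (d[rb] - R_free_disp) +
      sys$rim_mult * sum((1 - xiw) * fS)
    R[rt] <- R[rt] + cfg$k_rim_top * (d[rt] - R_free_disp) +
      sys$rim_mult * sum(xiw * fS)
    if (need_K) {
      K[rb, rb] <- K[rb, rb] + cfg$k_rim_bot
      K[rt, rt] <- K[rt, rt] + cfg$k_rim_top
    }
  } else if (need_K) {
    K[nr - 1L, nr - 1L] <- K[nr - 1L, nr - 1L] + 1   # inactive rim dofs
    K[nr, nr] <- K[nr, nr] + 1
  }

  list(R = R, K = K, ext_norm = ext_norm)
}

# Newton iteration at fixed load level; returns list(d, converged, ...)
newton_solve <- function(sys, d, sigma) {
  cfg <- sys$config
  free <- setdiff(seq_len(sys$n_red), unique(sys$dmap[sys$fixed]))
  # incremental follower loads: radial directions frozen at the
  # start-of-increment geometry
  dirs <- NULL
  if (isTRUE(sys$has_membrane)) {
    x0i <- node_positions(sys, d)
    rr <- sqrt(x0i[, 1L]^2 + x0i[, 2L]^2)
    dirs <- cbind(x0i[, 1L] / pmax(rr, 1e-9), x0i[, 2L] / pmax(rr, 1e-9))
  }
  res <- residual_system(sys, d, sigma, need_K = TRUE, radial_dirs = dirs)
  scale <- max(1, res$ext_norm)
  # Pseudo-transient continuation (automatic stabilization): an adaptive
  # viscous term c*I regularizes the loaded mechanism modes (free hinge,
  # adhesion peeling) and lets the iteration walk through local snap
  # configurations; c decays with the residual, so the final iterates are
  # plain Newton and the converged state carries no stabilization force.
  rn <- sqrt(sum(res$R[free]^2))
  cstab <- cfg$stab0 * max(1, rn)
  rn_best <- rn
  stall <- 0L
  for (it in seq_len(cfg$max_iter)) {
    if (rn <= cfg$tol * scale)
      return(list(d = d, converged = TRUE, iterations = it - 1L,
                  residual = rn))
    Kf <- res$K[free, free]
    diag(Kf) <- diag(Kf) + cstab
    step <- tryCatch(solve(Kf, -res$R[free]), error = function(e) NULL)
    if (is.null(step)) {
      cstab <- max(cstab, 1e-3) * 10
      if (cstab > 1e8)
        return(list(d = d, converged = FALSE, iterations = it,
                    residual = rn, message = "singular tangent"))
      next
    }
    smax <- max(abs(step))
    if (smax > cfg$step_max) step <- step * (cfg$step_max / smax)
    d_try <- d
    d_try[free] <- d[free] + step
    rn_try <- sqrt(sum(residual_system(sys, d_try, sigma, need_K = FALSE,
                                       radial_dirs = dirs)$R[free]^2))
    if (is.finite(rn_try) && rn_try < 1.5 * rn) {
      # accept (a limited transient increase is allowed near snaps) and
      # adapt the damping with the residual trend
      d <- d_try
      cstab <- max(cstab * min(max(rn_try / rn, 0.1), 0.9), 1e-9)
      rn <- rn_try
      res <- residual_system(sys, d, sigma, need_K = TRUE,
                             radial_dirs = dirs)
      rn <- sqrt(sum(res$R[free]^2))
    } else {
      cstab <- max(cstab, 1e-4) * 10
      if (cstab > 1e8)
        return(list(d = d, converged = FALSE, iterations = it,
                    residual = rn, message = "stabilization exhausted"))
    }
    if (rn < 0.999 * rn_best) {
      rn_best <- rn
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > 30L)
        return(list(d = d, converged = FALSE, iterations = it,
                    residual = rn, message = "no progress"))
    }
  }
  list(d = d, converged = rn <= cfg$tol * scale,
       iterations = cfg$max_iter, residual = rn,
       message = if (rn > cfg$tol * scale) "max iterations reached")
}

# snapshot of the solved state at one increment
make_state <- function(sys, d, sigma, nw) {
  stretch <- if (isTRUE(sys$has_membrane))
    areal_stretch(sys$patch, sigma) else 1
  h <- if (isTRUE(sys$has_membrane))
    sys$patch$rest_thickness / stretch else NA_real_
  structure(list(sigma = sigma, d = d,
                 positions = node_positions(sys, d),
                 rim_radius = if (isTRUE(sys$has_membrane))
                   sys$rim_R0 + d[sys$n_red - 1L] else NA_real_,
                 rim_radius_top = if (isTRUE(sys$has_membrane))
                   sys$rim_R0 + d[sys$n_red] else NA_real_,
                 thickness = h, stretch = stretch,
                 thinning_percent = if (isTRUE(sys$has_membrane))
                   100 * (1 - 1 / stretch) else NA_real_,
                 converged = nw$converged, iterations = nw$iterations,
                 residual = nw$residual),
            class = "system_state")
}

#' Quasi-static solve over a load ramp
#'
#' Ramps the nondimensional membrane tension from 0 to `sigma_max` in equal
#' increments, Newton-iterating to equilibrium at each level with the
#' previous solution as predictor. Increments are halved adaptively on
#' non-convergence (up to `max_halvings`); if the system still fails to
#' converge, the truncated trajectory is returned with a diagnostic, which
#' is how instability of a variant (e.g. the N-terminus deletion) is
#' reported rather than as an error.
#'
#' @param sys a `channel_system` from [assemble_system()].
#' @param config optional `solver_config` overriding the one in `sys`.
#' @return object of class `gating_trajectory`: list of `system_state`
#'   snapshots (`states`, the first at sigma* = 0), the system, and fields
#'   `completed` / `diagnostic`.
#' @export
solve_quasistatic <- function(sys, config = NULL) {
  if (!is.null(config)) sys$config <- config
  cfg <- sys$config
  d <- numeric(sys$n_red)
  states <- list(make_state(sys, d, 0,
                            list(converged = TRUE, iterations = 0L,
                                 residual = 0)))
  if (cfg$sigma_max > 0) {
    targets <- seq(0, cfg$sigma_max, length.out = cfg$n_increments + 1L)[-1L]
    sigma_prev <- 0
    diagnostic <- NULL
    for (tg in targets) {
      # adaptive sub-stepping toward each target level
      sig <- tg
      halvings <- 0L
      repeat {
        nw <- newton_solve(sys, d, sig)
        if (nw$converged) {
          d <- nw$d
          sigma_prev <- sig
          if (abs(sig - tg) < 1e-12) break
          sig <- tg
        } else {
          halvings <- halvings + 1L
          if (halvings > cfg$max_halvings) {
            diagnostic <- sprintf(
              "instability: no equilibrium found at sigma* = %.4f (last converged %.4f, residual %.3g, %s)",
              sig, sigma_prev, nw$residual,
              if (!is.null(nw$message)) nw$message else "diverged")
            break
          }
          sig <- sigma_prev + (sig - sigma_prev) / 2
        }
      }
      if (!is.null(diagnostic)) {
        traj <- structure(list(states = states, sys = sys,
                               completed = FALSE, diagnostic = diagnostic),
                          class = "gating_trajectory")
        return(traj)
      }
      states[[length(states) + 1L]] <- make_state(sys, d, tg, nw)
    }
  }
  structure(list(states = states, sys = sys, completed = TRUE,
                 diagnostic = NULL),
            class = "gating_trajectory")
}

#' @export
print.gating_trajectory <- function(x, ...) {
  ns <- length(x$states)
  cat(sprintf("<gating_trajectory> %d states, sigma* %.3f -> %.3f%s\n",
              ns, x$states[[1L]]$sigma, x$states[[ns]]$sigma,
              if (x$completed) "" else " (truncated)"))
  if (!is.null(x$diagnostic)) cat(" ", x$diagnostic, "\n")
  invisible(x)
}

#' Von Mises stress map of a solved state
#'
#' Equivalent (von Mises) stress of every beam element, from its axial
#' force, bending moments and twisting moment resultants, in units of the
#' protein Young's modulus E.
#'
#' @param sys a `channel_system`.
#' @param state a converged `system_state` from the trajectory.
#' @return data.frame with columns `element`, `class` (helix class),
#'   `subunit`, and `vm` (nondimensional von Mises stress).
#' @export
von_mises_map <- function(sys, state) {
  if (!isTRUE(state$converged)) stop("state is not converged")
  d <- state$d[sys$dmap]
  out <- data.frame(element = seq_along(sys$elements),
                    class = vapply(sys$elements, `[[`, "", "class"),
                    subunit = vapply(sys$elements, function(e)
                      as.integer(e$subunit), integer(1L)),
                    vm = 0)
  for (k in seq_along(sys$elements)) {
    el <- sys$elements[[k]]
    fl <- beam_internal_force(d[el$dofs], el$X0i, el$X0j, el)$f_l
    N <- fl[1L]
    Tw <- max(abs(fl[2L]), abs(fl[5L]))
    Mb <- max(sqrt(fl[3L]^2 + fl[4L]^2), sqrt(fl[6L]^2 + fl[7L]^2))
    sig <- abs(N) / el$A + Mb / el$W
    tau <- Tw * (sqrt(el$A / pi)) / (2 * el$I)   # T r / J with J = 2I
    out$vm[k] <- sqrt(sig^2 + 3 * tau^2)
  }
  out
}

#' Cantilever benchmark of the beam core
#'
#' Solves a straight cantilever of `n_elem` corotational beam elements
#' under a transverse tip load with the same Newton machinery as the
#' channel runs, and compares with the Euler-Bernoulli closed form
#' PL^3/3EI.
#'
#' @param n_elem number of elements.
#' @param load transverse tip load (dimensionless force).
#' @param length beam length (Angstrom).
#' @param diameter rod diameter (Angstrom).
#' @return list with `tip_deflection`, `closed_form`, `relative_error`.
#' @export
cantilever_benchmark <- function(n_elem = 10, load = 0.05, length = 40,
                                 diameter = 5) {
  sec <- rod_section(diameter)
  npts <- n_elem + 1L
  X0 <- cbind(seq(0, length, length.out = npts), 0, 0)
  E0 <- element_triad(c(1, 0, 0))
  elements <- list()
  dl <- length / n_elem
  for (k in seq_len(n_elem)) {
    el <- list(i = k, j = k + 1L, L0 = dl, E0 = E0, EA = sec$EA,
               EI = sec$EI, GJ = sec$GJ, A = sec$A, I = sec$I, W = sec$W,
               class = "TM1", subunit = 0L, rod = 1L)
    el$Kl <- local_stiffness(el)
    el$X0i <- X0[k, ]; el$X0j <- X0[k + 1L, ]
    el$dofs <- c(node_dofs(k), node_dofs(k + 1L))
    elements[[k]] <- el
  }
  sys <- structure(list(
    model = NULL, patch = NULL, law = NULL,
    config = solver_config(sigma_max = 1, n_increments = 1,
                           nodes_per_helix = max(4L, npts), k_reg = 0),
    X0 = X0, n_nodes = npts, n_dof = 6L * npts + 2L,
    node_rod = rep(1L, npts), node_class = rep("TM1", npts),
    node_subunit = rep(0L, npts),
    trib_len = rep(dl, npts), rod_radius = diameter / 2,
    rods = list(seq_len(npts)), elements = elements,
    springs = list(), hinges = list(),
    fixed = node_dofs(1L),
    point_loads = list(dofs = 6L * (npts - 1L) + 2L, values = load),
    has_membrane = FALSE), class = "channel_system")
  sys <- finalize_dof_map(sys)
  traj <- solve_quasistatic(sys)
  st <- traj$states[[length(traj$states)]]
  tip <- st$positions[npts, 2L]
  cf <- load * length^3 / (3 * sec$EI)
  list(tip_deflection = tip, closed_form = cf,
       relative_error = abs(tip - cf) / cf,
       converged = st$converged)
}
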