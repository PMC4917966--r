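# Gating observables computed from solved states and trajectories: helix
# tilts relative to the fivefold axis, the effective (backbone) pore
# radius, the N-terminal radial displacement, the N-term/TM1 continuity
# angle, and the WT / deletion / linker-extension comparison experiments.

refit_axis <- function(sys, state, name, subunit = 0) {
  fit_helix_axis(helix_node_positions(sys, state, name, subunit))
}

subunit_values <- function(sys, state, fun) {
  ns <- if (isTRUE(sys$symmetric)) 0 else 0:4
  vapply(ns, function(s) fun(s), numeric(1L))
}

#' Helix tilt relative to the fivefold axis
#'
#' Refits a straight axis to the deformed nodes of the selected helix in
#' each subunit and reports the angle between that axis and the fivefold
#' (+z) axis, averaged over subunits. For TM2 the N-to-C direction points
#' cytoplasmically; the tilt uses the membrane-outward sense of each axis
#' so values are comparable across helices.
#'
#' @param sys a `channel_system`.
#' @param state a converged `system_state`.
#' @param helix `"NTERM"`, `"TM1"` or `"TM2"`.
#' @return list with `mean` (degrees), `sd` (0 for symmetry-reduced
#'   solves), and `per_subunit`.
#' @export
tilt_to_axis <- function(sys, state, helix = "TM1") {
  if (!isTRUE(state$converged)) stop("state is not converged")
  vals <- subunit_values(sys, state, function(s) {
    dirv <- refit_axis(sys, state, helix, s)$axis_direction
    if (dirv[3L] < 0) dirv <- -dirv
    vec_angle(dirv, c(0, 0, 1))
  })
  if (isTRUE(sys$symmetric)) vals <- rep(vals, 5L)
  list(mean = mean(vals), sd = stats::sd(vals), per_subunit = vals)
}

#' Effective pore radius of a state
#'
#' Backbone-based pore size: the minimum over membrane-depth slices of the
#' distance from the fivefold axis to the nearest TM1 rod centerline, minus
#' the rod radius. Side chains are not represented, so this is the
#' effective (backbone envelope) pore, not the physiological constriction.
#'
#' @param sys a `channel_system`.
#' @param state a converged `system_state`.
#' @param dz slice spacing in Angstrom (default 0.25).
#' @param z_range optional `c(zlo, zhi)`; defaults to the current membrane
#'   span.
#' @return list with `radius`, `diameter` (Angstrom), and `z_min` (depth of
#'   the constriction); the radius is clamped at zero if the rods overlap
#'   the axis.
#' @export
effective_pore_radius <- function(sys, state, dz = 0.25, z_range = NULL) {
  if (!any(sys$node_class == "TM1")) stop("no TM1 segments in the system")
  h <- if (is.finite(state$thickness)) state$thickness
       else sys$patch$rest_thickness
  if (is.null(z_range)) z_range <- c(-h / 2, h / 2)
  zs <- seq(z_range[1L], z_range[2L], by = dz)
  nsub <- if (isTRUE(sys$symmetric)) 0 else 0:4
  rmin <- Inf
  zmin <- NA_real_
  for (s in nsub) {
    pts <- resample_polyline(helix_node_positions(sys, state, "TM1", s))
    for (z in zs) {
      for (i in seq_len(nrow(pts) - 1L)) {
        z1 <- pts[i, 3L]; z2 <- pts[i + 1L, 3L]
        if ((z1 - z) * (z2 - z) <= 0 && abs(z2 - z1) > 1e-12) {
          t <- (z - z1) / (z2 - z1)
          p <- pts[i, ] * (1 - t) + pts[i + 1L, ] * t
          r <- sqrt(p[1L]^2 + p[2L]^2)
          if (r < rmin) { rmin <- r; zmin <- z }
        }
      }
    }
  }
  radius <- max(rmin - sys$rod_radius, 0)
  list(radius = radius, diameter = 2 * radius, z_min = zmin)
}

#' Radial displacement of a helix along a trajectory
#'
#' Change in the cylindrical radius of the helix midpoint between the first
#' and last states of a trajectory, averaged over subunits.
#'
#' @param traj a `gating_trajectory` with at least 2 states.
#' @param helix helix class (default `"NTERM"`).
#' @return list with `mean` (Angstrom, positive = outward), `sd`, and
#'   `per_subunit`.
#' @export
radial_displacement <- function(traj, helix = "NTERM") {
  if (length(traj$states) < 2L) stop("trajectory needs at least 2 states")
  sys <- traj$sys
  st0 <- traj$states[[1L]]
  st1 <- traj$states[[length(traj$states)]]
  midr <- function(state, s) {
    pts <- helix_node_positions(sys, state, helix, s)
    cyl_radius(colMeans(pts[c(floor((nrow(pts) + 1) / 2),
                              ceiling((nrow(pts) + 1) / 2)), , drop = FALSE]))
  }
  ns <- if (isTRUE(sys$symmetric)) 0 else 0:4
  vals <- vapply(ns, function(s) midr(st1, s) - midr(st0, s), numeric(1L))
  if (isTRUE(sys$symmetric)) vals <- rep(vals, 5L)
  list(mean = mean(vals), sd = stats::sd(vals), per_subunit = vals)
}

#' N-term/TM1 continuity angle
#'
#' The interior angle of the G14 elbow: the angle between the two arms
#' leaving the junction (toward the N-terminal M1 end and toward the TM1
#' periplasmic end). A straight, contiguous N-term+TM1 helix reads 180
#' degrees; the closed crystal-like geometry reads about 95 degrees. The
#' trend of this angle toward 180 along a loading ramp is the formation of
#' the contiguous helix in the open state.
#'
#' @param sys a `channel_system`.
#' @param state a converged `system_state`.
#' @param subunit subunit index.
#' @return angle in degrees.
#' @export
continuity_angle <- function(sys, state, subunit = 0) {
  if (!any(sys$node_class == "NTERM"))
    stop("no N-terminal helix in the system (deletion variant)")
  dnt <- refit_axis(sys, state, "NTERM", subunit)$axis_direction
  d1 <- refit_axis(sys, state, "TM1", subunit)$axis_direction
  vec_angle(-dnt, d1)
}

#' Gating report for a trajectory
#'
#' Per-increment table of the headline gating observables.
#'
#' @param traj a `gating_trajectory`.
#' @return data.frame with one row per converged increment: `sigma`,
#'   `tm1_tilt`, `tm1_tilt_change`, `tm2_tilt`, `tm2_tilt_change`,
#'   `continuity_angle` (NA without N terminus), `pore_radius`,
#'   `pore_diameter`, `nterm_radial_displacement` (cumulative from rest),
#'   `thinning_percent`, `rim_displacement`, and `max_vm_class` (helix
#'   class carrying the maximum von Mises stress; NA at zero load).
#' @export
gating_report <- function(traj) {
  sys <- traj$sys
  has_nt <- any(sys$node_class == "NTERM")
  st0 <- traj$states[[1L]]
  tm1_0 <- tilt_to_axis(sys, st0, "TM1")$mean
  tm2_0 <- tilt_to_axis(sys, st0, "TM2")$mean
  midr0 <- if (has_nt) radial_midpoint(sys, st0, "NTERM") else NA_real_
  rows <- lapply(traj$states, function(st) {
    t1 <- tilt_to_axis(sys, st, "TM1")$mean
    t2 <- tilt_to_axis(sys, st, "TM2")$mean
    pr <- effective_pore_radius(sys, st)
    vm <- if (st$sigma > 0) von_mises_map(sys, st) else NULL
    data.frame(
      sigma = st$sigma,
      tm1_tilt = t1, tm1_tilt_change = t1 - tm1_0,
      tm2_tilt = t2, tm2_tilt_change = t2 - tm2_0,
      continuity_angle = if (has_nt) continuity_angle(sys, st) else NA_real_,
      pore_radius = pr$radius, pore_diameter = pr$diameter,
      nterm_radial_displacement = if (has_nt)
        radial_midpoint(sys, st, "NTERM") - midr0 else NA_real_,
      thinning_percent = st$thinning_percent,
      rim_displacement = st$rim_radius - sys$rim_R0,
      max_vm_class = if (is.null(vm)) NA_character_ else {
        agg <- tapply(vm$vm, vm$class, max)
        names(agg)[which.max(agg)]
      },
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Smooth (spline) resampling of a rod centerline polyline, so slightly
# bent rods are represented consistently across mesh densities (a coarse
# linear polyline cuts the corners of a curved rod).
resample_polyline <- function(pts, factor = 8L) {
  n <- nrow(pts)
  if (n < 3L) return(pts)
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  ss <- seq(0, s[n], length.out = (n - 1L) * factor + 1L)
  cbind(stats::spline(s, pts[, 1L], xout = ss)$y,
        stats::spline(s, pts[, 2L], xout = ss)$y,
        stats::spline(s, pts[, 3L], xout = ss)$y)
}

radial_midpoint <- function(sys, state, helix) {
  pts <- helix_node_positions(sys, state, helix, 0)
  cyl_radius(colMeans(pts[c(floor((nrow(pts) + 1) / 2),
                            ceiling((nrow(pts) + 1) / 2)), , drop = FALSE]))
}

#' Run a gating experiment for a channel variant
#'
#' Builds the requested variant of the idealized channel (wild type, the
#' N-terminus deletion, or a +2G / +5G glycine-linker extension), ramps the
#' nondimensional membrane tension to `sigma_max`, and returns the gating
#' report together with a matched wild-type run for comparison.
#'
#' @param variant one of `"WT"`, `"dNTERM"`, `"+2G"`, `"+5G"`.
#' @param sigma_max final nondimensional tension.
#' @param config a `solver_config` (frozen default calibration if omitted).
#' @param params an `idealized_params` set (gating preset by default).
#' @param patch a `bilayer_patch`.
#' @param law a `vdw_law`.
#' @param compare_wt if TRUE (default) also run the matched WT reference.
#' @return object of class `variant_experiment`: list with `variant`,
#'   `trajectory`, `report`, and (unless `compare_wt = FALSE` or the
#'   variant is WT) `wt_trajectory`, `wt_report`.
#' @export
run_variant_experiment <- function(variant = c("WT", "dNTERM", "+2G", "+5G"),
                                   sigma_max = 0.6, config = NULL,
                                   params = idealized_params("gating"),
                                   patch = bilayer_patch(), law = vdw_law(),
                                   compare_wt = TRUE) {
  variant <- match.arg(variant)
  if (is.null(config)) config <- solver_config(sigma_max = sigma_max)
  else config$sigma_max <- sigma_max
  build_variant <- function(v) {
    if (v == "dNTERM") return(build_idealized(params, has_nterm = FALSE))
    p <- params
    p$linker_extension <- switch(v, "WT" = 0L, "+2G" = 2L, "+5G" = 5L)
    build_idealized(p)
  }
  model <- build_variant(variant)
  sys <- assemble_system(model, patch, law, config)
  traj <- solve_quasistatic(sys)
  out <- list(variant = variant, trajectory = traj,
              report = gating_report(traj))
  if (compare_wt && variant != "WT") {
    wt_sys <- assemble_system(build_variant("WT"), patch, law, config)
    wt_traj <- solve_quasistatic(wt_sys)
    out$wt_trajectory <- wt_traj
    out$wt_report <- gating_report(wt_traj)
  }
  class(out) <- "variant_experiment"
  out
}

#' @export
print.variant_experiment <- function(x, ...) {
  rep <- x$report
  last <- rep[nrow(rep), ]
  cat(sprintf("<variant_experiment> %s: sigma* -> %.3f%s\n", x$variant,
              last$sigma,
              if (x$trajectory$completed) "" else " (unstable, truncated)"))
  cat(sprintf("  pore diameter %.1f A, TM1 tilt %.1f deg (change %.1f), thinning %.1f%%\n",
              last$pore_diameter, last$tm1_tilt, last$tm1_tilt_change,
              last$thinning_percent))
  if (!is.null(x$wt_report)) {
    wt <- x$wt_report
    wt_at <- wt[which.min(abs(wt$sigma - last$sigma)), ]
    cat(sprintf("  matched WT at sigma* %.3f: pore %.1f A, TM1 tilt %.1f deg\n",
                wt_at$sigma, wt_at$pore_diameter, wt_at$tm1_tilt))
  }
  invisible(x)
}

#' Mesh sensitivity study
#'
#' Reruns the WT gating problem at increasing mesh density (nodes per
#' helix) and reports how the key observables change on refinement,
#' identifying the coarsest level at which the TM1 tilt and pore radius
#' change by less than the given tolerance on further refinement.
#'
#' @param levels integer vector of nodes-per-helix values (>= 3 levels).
#' @param sigma_max load level for the comparison.
#' @param config base `solver_config`.
#' @param params,patch,law model inputs as in [run_variant_experiment()].
#' @param tol_percent convergence threshold (percent change on refinement).
#' @return data.frame with one row per level (`nodes_per_helix`,
#'   `tm1_tilt`, `pore_radius`, `n_elements`, percentage changes), with
#'   attribute `converged_level`.
#' @export
mesh_sensitivity <- function(levels = c(6, 8, 12, 16), sigma_max = 0.3,
                             config = solver_config(),
                             params = idealized_params("gating"),
                             patch = bilayer_patch(), law = vdw_law(),
                             tol_percent = 2) {
  if (length(levels) < 3L) stop("need at least 3 refinement levels")
  levels <- sort(as.integer(levels))
  rows <- lapply(levels, function(np) {
    cfg <- config
    cfg$nodes_per_helix <- np
    cfg$sigma_max <- sigma_max
    sys <- assemble_system(build_idealized(params), patch, law, cfg)
    traj <- solve_quasistatic(sys)
    st <- traj$states[[length(traj$states)]]
    data.frame(nodes_per_helix = np,
               n_elements = length(sys$elements),
               sigma_reached = st$sigma,
               tm1_tilt = tilt_to_axis(sys, st, "TM1")$mean,
               # fine z-scan so slice quantization does not masquerade as
               # mesh sensitivity
               pore_radius = effective_pore_radius(sys, st,
                                                   dz = 0.02)$radius)
  })
  out <- do.call(rbind, rows)
  out$tilt_change_pct <- c(NA, abs(diff(out$tm1_tilt)) /
                             pmax(abs(out$tm1_tilt[-nrow(out)]), 1e-9) * 100)
  out$pore_change_pct <- c(NA, abs(diff(out$pore_radius)) /
                             pmax(abs(out$pore_radius[-nrow(out)]), 1e-9) * 100)
  conv <- which(out$tilt_change_pct[-1L] < tol_percent &
                  out$pore_change_pct[-1L] < tol_percent)
  attr(out, "converged_level") <-
    if (length(conv) > 0L) out$nodes_per_helix[min(conv)] else NA_integer_
  out
}
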