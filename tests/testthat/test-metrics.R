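test_that("tilt is measured against the fivefold axis", {
  # rest fixture: TM1 built at a declared tilt reads back exactly
  p <- idealized_params("gating", tilts = list(tm1_tilt = 28, tm2_tilt = 14,
                                               dir_azimuth_offset = 95))
  sys <- assemble_system(build_idealized(p))
  st <- synthetic_state(sys, sys$X0)
  expect_equal(tilt_to_axis(sys, st, "TM1")$mean, 28, tolerance = 1e-6)
  expect_equal(tilt_to_axis(sys, st, "TM2")$mean, 14, tolerance = 1e-6)

  # constructed rotation oracle: rotating the nodes about a horizontal axis
  # in the tilt plane adds exactly to the tilt
  sel <- which(sys$node_class == "TM1")
  dirv <- rodgate:::unit3(sys$X0[sel[8L], ] - sys$X0[sel[1L], ])
  horiz <- rodgate:::unit3(rodgate:::cross3(c(0, 0, 1), dirv))
  R <- rotation_about(horiz, 12)    # opens the angle to +z by 12 degrees
  pos <- sys$X0
  pos[sel, ] <- t(R %*% t(sys$X0[sel, ]))
  st2 <- synthetic_state(sys, pos)
  expect_equal(tilt_to_axis(sys, st2, "TM1")$mean, 40, tolerance = 1e-6)

  bad <- st; bad$converged <- FALSE
  expect_error(tilt_to_axis(sys, bad), "not converged")
})

test_that("pore radius equals the construction for vertical rods", {
  # five vertical TM1 rods at centerline radius 14.5: radius 12, diam 24
  p <- idealized_params("gating",
                        tilts = list(tm1_tilt = 0, tm2_tilt = 14,
                                     dir_azimuth_offset = 95),
                        tm1_bottom_radius = 14.5)
  sys <- assemble_system(build_idealized(p, has_nterm = FALSE))
  st <- synthetic_state(sys, sys$X0)
  pr <- effective_pore_radius(sys, st)
  expect_equal(pr$radius, 12, tolerance = 1e-9)
  expect_equal(pr$diameter, 24, tolerance = 1e-9)
})

test_that("the z-scan matches a brute-force dense sampling oracle", {
  run <- wt_half_state()
  sys <- wt_full_run()$sys
  pr <- effective_pore_radius(sys, run)
  # brute force: dense point sampling of every TM1 centerline (same
  # smooth resampled centerline as the metric, scanned without slicing)
  rmin <- Inf
  for (s in 0:4) {
    pts <- rodgate:::resample_polyline(helix_node_positions(sys, run,
                                                            "TM1", s))
    for (i in seq_len(nrow(pts) - 1L)) {
      tt <- seq(0, 1, length.out = 400L)
      seg <- outer(1 - tt, pts[i, ]) + outer(tt, pts[i + 1L, ])
      keep <- abs(seg[, 3L]) <= run$thickness / 2
      if (any(keep))
        rmin <- min(rmin, sqrt(seg[keep, 1L]^2 + seg[keep, 2L]^2))
    }
  }
  expect_equal(pr$radius, max(rmin - sys$rod_radius, 0), tolerance = 0.05)
})

test_that("radial displacement reads rigid radial translations exactly", {
  sys <- assemble_system(build_idealized(idealized_params("gating")))
  st0 <- synthetic_state(sys, sys$X0)
  # push all N-term nodes 6 A radially outward
  pos <- sys$X0
  sel <- which(sys$node_class == "NTERM")
  r <- sqrt(pos[sel, 1L]^2 + pos[sel, 2L]^2)
  pos[sel, 1:2] <- pos[sel, 1:2] * (1 + 6 / r)
  st1 <- synthetic_state(sys, pos)
  traj <- structure(list(states = list(st0, st1), sys = sys,
                         completed = TRUE, diagnostic = NULL),
                    class = "gating_trajectory")
  rd <- radial_displacement(traj, "NTERM")
  # midpoint radius averages two nodes, so exactness is up to the small
  # chord-vs-arc difference of the two middle nodes
  expect_equal(rd$mean, 6, tolerance = 1e-3)
  # identical first and last state: zero
  traj0 <- structure(list(states = list(st0, st0), sys = sys,
                          completed = TRUE, diagnostic = NULL),
                     class = "gating_trajectory")
  expect_equal(radial_displacement(traj0, "NTERM")$mean, 0)
  expect_error(radial_displacement(structure(list(states = list(st0),
                                                  sys = sys),
                                             class = "gating_trajectory")),
               "2 states")
})

test_that("the continuity angle reads the elbow convention", {
  sys <- assemble_system(build_idealized(idealized_params("gating")))
  st <- synthetic_state(sys, sys$X0)
  expect_equal(continuity_angle(sys, st), 95, tolerance = 0.01)
  # collinear constructed arms: 180 degrees
  pos <- sys$X0
  sel_nt <- which(sys$node_class == "NTERM")
  sel_t1 <- which(sys$node_class == "TM1")
  d1 <- rodgate:::unit3(pos[sel_t1[8L], ] - pos[sel_t1[1L], ])
  hinge <- pos[sel_t1[1L], ]
  for (k in seq_along(sel_nt))
    pos[sel_nt[k], ] <- hinge - (8L - k) * 2.8 * d1
  st2 <- synthetic_state(sys, pos)
  expect_equal(continuity_angle(sys, st2), 180, tolerance = 0.01)

  sdn <- assemble_system(build_idealized(idealized_params("gating"),
                                         has_nterm = FALSE))
  expect_error(continuity_angle(sdn, synthetic_state(sdn, sdn$X0)),
               "deletion")
})

test_that("the open state straightens the N-term/TM1 elbow", {
  run <- wt_full_run()
  closed <- continuity_angle(run$sys, run$traj$states[[1L]])
  open <- continuity_angle(run$sys,
                           run$traj$states[[length(run$traj$states)]])
  expect_gt(open, closed)
})

test_that("gating metrics are invariant under global rotation", {
  run <- wt_full_run()
  st <- wt_half_state()
  pr0 <- effective_pore_radius(run$sys, st)$radius
  t0 <- tilt_to_axis(run$sys, st, "TM1")$mean
  R <- rotation_z(23.7)
  st2 <- st
  st2$positions <- t(R %*% t(st$positions))
  expect_equal(effective_pore_radius(run$sys, st2)$radius, pr0,
               tolerance = 1e-6)
  expect_equal(tilt_to_axis(run$sys, st2, "TM1")$mean, t0, tolerance = 1e-6)
})

test_that("pore radius grows monotonically along the WT ramp", {
  run <- wt_full_run()
  pores <- vapply(run$traj$states, function(st)
    effective_pore_radius(run$sys, st)$radius, numeric(1L))
  expect_true(all(diff(pores) > -1e-6))
})

test_that("variant experiments order the pore sizes as expected", {
  run <- wt_full_run()
  st_wt <- wt_half_state()
  pore_wt <- effective_pore_radius(run$sys, st_wt)$radius

  dn <- dn_half_run()
  st_dn <- dn$traj$states[[length(dn$traj$states)]]
  pore_dn <- effective_pore_radius(dn$sys, st_dn)$radius
  expect_lt(pore_dn, pore_wt)

  cfg <- solver_config(sigma_max = 0.3, n_increments = 15)
  g5 <- run_variant_experiment("+5G", sigma_max = 0.3, config = cfg,
                               compare_wt = FALSE)
  pore_5g <- g5$report$pore_radius[nrow(g5$report)]
  expect_lt(pore_5g, pore_wt)
  expect_gt(pore_5g, pore_dn)
})

test_that("a WT experiment equals the plain WT run", {
  cfg <- solver_config(sigma_max = 0.05, n_increments = 2)
  a <- run_variant_experiment("WT", sigma_max = 0.05, config = cfg,
                              compare_wt = FALSE)
  sys <- assemble_system(build_idealized(idealized_params("gating")),
                         config = cfg)
  b <- gating_report(solve_quasistatic(sys))
  expect_equal(a$report, b, tolerance = 1e-12)
})
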