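small_cfg <- function(...) {
  solver_config(sigma_max = 0.05, n_increments = 2, ...)
}

test_that("system assembly counts match the model", {
  m <- build_idealized(idealized_params("gating"))
  # full (unreduced) pentamer
  sys <- assemble_system(m, config = solver_config(symmetry = FALSE))
  expect_equal(sys$n_nodes, 15L * 8L)
  expect_length(sys$elements, 15L * 7L)
  expect_length(sys$hinges, 5L)
  expect_length(Filter(function(s) s$type == "loop", sys$springs), 5L)
  # symmetry-reduced: one subunit
  red <- assemble_system(m)
  expect_equal(red$n_nodes, 3L * 8L)
  expect_length(red$elements, 3L * 7L)
  expect_length(red$hinges, 1L)

  mdn <- build_idealized(idealized_params("gating"), has_nterm = FALSE)
  sdn <- assemble_system(mdn, config = solver_config(symmetry = FALSE))
  expect_length(sdn$elements, 10L * 7L)
  expect_length(sdn$hinges, 0L)
})

test_that("glycine-linker variants replace the hinge by a slack connector", {
  p <- idealized_params("gating", linker_extension = 5L)
  sys <- assemble_system(build_idealized(p))
  expect_length(sys$hinges, 0L)
  lk <- Filter(function(s) s$type == "linker", sys$springs)
  expect_length(lk, 1L)
  expect_equal(lk[[1L]]$rest_len, 5 * 1.5)
  p2 <- idealized_params("gating", linker_extension = 2L)
  lk2 <- Filter(function(s) s$type == "linker",
                assemble_system(build_idealized(p2))$springs)
  expect_equal(lk2[[1L]]$rest_len, 2 * 1.5)
})

test_that("zero load leaves the rest geometry untouched", {
  sys <- assemble_system(build_idealized(idealized_params("gating")),
                         config = solver_config(sigma_max = 0))
  traj <- solve_quasistatic(sys)
  expect_length(traj$states, 1L)
  st <- traj$states[[1L]]
  expect_equal(st$positions, sys$X0, tolerance = 1e-12)
  expect_true(st$converged)
  # and the residual at rest is numerically zero
  res <- rodgate:::residual_system(sys, numeric(sys$n_red), 0, need_K = FALSE)
  expect_lt(max(abs(res$R)), 1e-8)
})

test_that("the solver is deterministic", {
  m <- build_idealized(idealized_params("gating"))
  cfg <- small_cfg()
  t1 <- solve_quasistatic(assemble_system(m, config = cfg))
  t2 <- solve_quasistatic(assemble_system(m, config = cfg))
  s1 <- t1$states[[length(t1$states)]]
  s2 <- t2$states[[length(t2$states)]]
  expect_identical(s1$d, s2$d)
  expect_identical(s1$positions, s2$positions)
})

test_that("the full pentamer solve is C5 equivariant", {
  m <- build_idealized(idealized_params("gating"))
  cfg <- small_cfg(symmetry = FALSE)
  traj <- solve_quasistatic(assemble_system(m, config = cfg))
  sys <- traj$sys
  st <- traj$states[[length(traj$states)]]
  expect_true(st$converged)
  R72 <- rotation_z(72)
  for (name in c("NTERM", "TM1", "TM2")) {
    for (k in 0:4) {
      a <- st$positions[which(sys$node_class == name &
                                sys$node_subunit == k), ]
      b <- st$positions[which(sys$node_class == name &
                                sys$node_subunit == (k + 1) %% 5), ]
      expect_lt(max(abs(t(R72 %*% t(a)) - b)), 1e-4)
    }
  }
})

test_that("symmetry reduction agrees with the full solve", {
  m <- build_idealized(idealized_params("gating"))
  full <- solve_quasistatic(assemble_system(m, config = small_cfg(symmetry = FALSE)))
  red <- solve_quasistatic(assemble_system(m, config = small_cfg()))
  stf <- full$states[[length(full$states)]]
  str_ <- red$states[[length(red$states)]]
  af <- stf$positions[which(full$sys$node_class == "TM1" &
                              full$sys$node_subunit == 0L), ]
  ar <- helix_node_positions(red$sys, str_, "TM1", 0)
  expect_equal(af, ar, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("dimensionless outputs are independent of the modulus scale", {
  m <- build_idealized(idealized_params("gating"))
  cfg <- small_cfg()
  law1 <- vdw_law(a_h = 21, youngs_modulus = 2e8)
  law2 <- vdw_law(a_h = 21 * 3.7, youngs_modulus = 2e8 * 3.7)
  t1 <- solve_quasistatic(assemble_system(m, law = law1, config = cfg))
  t2 <- solve_quasistatic(assemble_system(m, law = law2, config = cfg))
  d1 <- t1$states[[length(t1$states)]]$d
  d2 <- t2$states[[length(t2$states)]]$d
  expect_lt(max(abs(d1 - d2)), 1e-10)
})

test_that("von Mises stresses are zero at rest and exact for pure axial", {
  sys <- assemble_system(build_idealized(idealized_params("gating")),
                         config = solver_config(sigma_max = 0))
  traj <- solve_quasistatic(sys)
  vm <- von_mises_map(sys, traj$states[[1L]])
  expect_true(all(vm$vm < 1e-10))
  expect_true(all(vm$vm >= 0))

  # single element under pure axial force: sigma_vm = N / A
  el <- c(list(L0 = 5, E0 = element_triad(c(0, 0, 1)),
               X0i = c(0, 0, 0), X0j = c(0, 0, 5)), rod_section(5))
  d12 <- numeric(12L); d12[9L] <- 0.02
  out <- beam_element_response(el, d12)
  N <- out$f_l[1L]
  expect_equal(N / el$A, el$EA * 0.02 / 5 / el$A, tolerance = 1e-9)

  # stress query on an unconverged state errors
  bad <- traj$states[[1L]]; bad$converged <- FALSE
  expect_error(von_mises_map(sys, bad), "not converged")
})
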