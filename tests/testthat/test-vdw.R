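test_that("the traction law has the stated equilibrium and sign structure", {
  law <- vdw_law()
  expect_equal(vdw_traction(law$d0, law), 0)
  # hand evaluation of the closed form at D = 2 D0 (inside the taper-free
  # region): S = s0 ((1/2)^3 - (1/2)^9)
  expect_equal(vdw_traction(2 * law$d0, law),
               law$s0 * ((1 / 2)^3 - (1 / 2)^9), tolerance = 1e-12)
  expect_gt(vdw_traction(1.5 * law$d0, law), 0)   # attraction beyond D0
  expect_lt(vdw_traction(0.8 * law$d0, law), 0)   # repulsion below D0
  # decay: essentially zero at the cutoff
  expect_lt(abs(vdw_traction(law$cutoff - 1e-6, law)),
            1e-3 * abs(vdw_traction(1.2 * law$d0, law)))
  expect_equal(vdw_traction(law$cutoff + 1, law), 0)
  expect_error(vdw_traction(-1, law), "positive")
})

test_that("traction integrates to the closed-form interaction energy", {
  law <- vdw_law()
  a <- law$taper_start          # compare on the untapered range
  for (D in c(2.2, 3, 4, 6)) {
    # U(D) = -int_D^cutoff S, so int_D^a S = U(a) - U(D)
    num <- stats::integrate(function(x) vdw_traction(x, law), D, a,
                            subdivisions = 2000L, rel.tol = 1e-10)$value
    ana <- vdw_energy(a, law) - vdw_energy(D, law)
    expect_equal(num, ana, tolerance = 1e-3 * max(abs(ana), 1e-12))
  }
  # minimum of the energy at the equilibrium separation
  D <- seq(1.5, 8, by = 0.01)
  expect_equal(D[which.min(vdw_energy(D, law))], law$d0, tolerance = 0.02)
})

test_that("Hamaker fitting recovers generating parameters", {
  truth <- vdw_law(a_h = 21, d0 = 3)
  fit <- fit_hamaker(synthetic_energy_table(truth))
  expect_equal(fit$a_h, 21, tolerance = 0.1 / 21)
  expect_equal(fit$d0, 3, tolerance = 1e-3)
  expect_lt(attr(fit, "residual_norm"), 1e-8)
})

test_that("Hamaker fitting is robust to multiplicative noise", {
  truth <- vdw_law(a_h = 21, d0 = 3)
  set.seed(11)
  est <- replicate(20, {
    fit_hamaker(synthetic_energy_table(truth, noise_sd = 0.05))$a_h
  })
  expect_lt(abs(mean(est) - 21), 3)
})

test_that("degenerate energy tables are rejected", {
  expect_error(energy_distance_table(1:4, rep(-1, 4)), "at least 5")
  expect_error(energy_distance_table(c(1, 2, 2, 3, 4), rep(-1, 5)),
               "strictly increasing")
})

test_that("tractions are invariant to the absolute modulus scale", {
  # multiplying E and A_H by a common factor leaves the nondimensional
  # traction identical
  a <- vdw_law(a_h = 21, youngs_modulus = 2e8)
  b <- vdw_law(a_h = 21 * 7.3, youngs_modulus = 2e8 * 7.3)
  D <- seq(1, 12, by = 0.25)
  expect_equal(vdw_traction(D, a), vdw_traction(D, b), tolerance = 1e-12)
})

test_that("contact tractions respect equilibrium and Newton's third law", {
  law <- vdw_law()
  # all gaps at D0: zero total force
  pos <- cbind(10, 0, 0)
  out <- contact_tractions(pos, rim_radius = 10 + 2.5 + law$d0, law, 1)
  expect_equal(out$forces, matrix(0, 1, 3), tolerance = 1e-12)
  expect_equal(out$rim_force, 0, tolerance = 1e-12)
  # single node at gap 2 D0, unit area: force equals the traction exactly
  out2 <- contact_tractions(pos, rim_radius = 10 + 2.5 + 2 * law$d0, law, 1)
  expect_equal(out2$forces[1, 1], vdw_traction(2 * law$d0, law))
  expect_equal(out2$rim_force, -sum(out2$forces[, 1]), tolerance = 1e-12)
  # sign flips across the equilibrium separation
  out3 <- contact_tractions(pos, rim_radius = 10 + 2.5 + 0.5 * law$d0, law, 1)
  expect_lt(out3$forces[1, 1], 0)
})
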