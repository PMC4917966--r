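test_that("the crystal-preset pentamer reproduces the printed geometry", {
  m <- build_idealized(idealized_params("crystal"))
  meas <- model_measurements(m)
  expect_equal(meas$xang_tm1_tm1_adj, -43, tolerance = 0.02)
  expect_equal(meas$xang_tm1_tm2_adj_reduced, 11, tolerance = 0.05)
  expect_equal(meas$ia_tm1_tm2_same, 135, tolerance = 0.02)
  expect_equal(meas$ia_tm1_tm2_adj, 169, tolerance = 0.02)
  expect_equal(meas$tm2_gap, 20, tolerance = 0.02)
  expect_equal(meas$nterm_link, 95, tolerance = 0.02)
})

test_that("idealized builds are exactly C5 symmetric", {
  m <- build_idealized(idealized_params("gating"))
  R <- rotation_z(72)
  for (name in c("NTERM", "TM1", "TM2")) {
    for (k in 0:4) {
      a <- get_segment(m, name, k)
      b <- get_segment(m, name, (k + 1) %% 5)
      expect_equal(as.numeric(R %*% a$axis_point), b$axis_point,
                   tolerance = 1e-6)
      expect_equal(as.numeric(R %*% a$axis_direction), b$axis_direction,
                   tolerance = 1e-9)
    }
  }
})

test_that("measurement ops invert the idealized build (round-trip)", {
  p <- idealized_params("gating")
  m <- build_idealized(p)
  meas <- model_measurements(m)
  expect_equal(meas$tm1_tilt, p$tilts$tm1_tilt, tolerance = 1e-9)
  expect_equal(meas$tm2_tilt, p$tilts$tm2_tilt, tolerance = 1e-9)
  expect_equal(meas$tm2_gap, p$tm2_gap, tolerance = 1e-6)
  expect_equal(meas$nterm_link, p$nterm_link_angle, tolerance = 1e-6)
})

test_that("metrics are invariant under global rotation about z", {
  m <- build_idealized(idealized_params("gating"))
  m2 <- m
  R <- rotation_z(37.3)
  m2$helices <- lapply(m$helices, transform_segment, R = R)
  a <- model_measurements(m); b <- model_measurements(m2)
  for (nm in names(a)) expect_equal(a[[nm]], b[[nm]], tolerance = 1e-8)
})

test_that("the N-terminus deletion drops the right components", {
  m <- build_idealized(idealized_params("gating"), has_nterm = FALSE)
  expect_length(m$helices, 10L)
  expect_length(m$hinges, 0L)
  expect_false(m$has_nterm)
  expect_error(get_segment(m, "NTERM", 0), "without the N terminus")
})

test_that("infeasible geometric constraints raise named errors", {
  p <- idealized_params("crystal")
  p$angles$xang_tm1_tm1 <- -170     # impossible under C5
  expect_error(build_idealized(p), "infeasible|cannot be realized")
  p2 <- idealized_params("gating", tm2_gap = 200)
  expect_error(build_idealized(p2), "gap")
})

test_that("a fixture PDB round-trips through the structure reader", {
  tmp <- tempfile(fileext = ".pdb")
  p <- idealized_params("crystal")
  # collinear C-alpha trace: fit is exact
  generate_fixture("idealized_pdb", tmp, params = p, helix_radius = 0)
  m2 <- build_from_structure(tmp)
  ref <- model_measurements(build_idealized(p))
  got <- model_measurements(m2)
  expect_equal(got$xang_tm1_tm1_adj, ref$xang_tm1_tm1_adj, tolerance = 0.1)
  expect_equal(got$tm2_gap, ref$tm2_gap, tolerance = 1e-3)
  expect_equal(got$nterm_link, ref$nterm_link, tolerance = 0.1)

  # realistic helical trace: within the helix-fit tolerance
  generate_fixture("idealized_pdb", tmp, params = p, helix_radius = 2.3)
  got2 <- model_measurements(build_from_structure(tmp))
  expect_equal(got2$xang_tm1_tm1_adj, ref$xang_tm1_tm1_adj, tolerance = 1.5)
  expect_equal(got2$ia_tm1_tm2_same, ref$ia_tm1_tm2_same, tolerance = 1.5)
  unlink(tmp)
})

test_that("missing residues in a structure are reported by name", {
  tmp <- tempfile(fileext = ".pdb")
  generate_fixture("idealized_pdb", tmp, helix_radius = 0)
  lines <- readLines(tmp)
  # drop residues 20-22 of chain A
  drop <- grepl("^ATOM", lines) & grepl(" A ", lines, fixed = TRUE) &
    substr(lines, 23, 26) %in% sprintf("%4d", 20:22)
  writeLines(lines[!drop], tmp)
  expect_error(build_from_structure(tmp), "missing residue")
  expect_error(build_from_structure(tmp), "20")
  unlink(tmp)
})
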