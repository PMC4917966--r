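test_that("axis fitting recovers exact and helical geometries", {
  # points exactly on the z-axis, 1.5 A apart
  f <- fit_helix_axis(cbind(0, 0, seq(0, 13.5, by = 1.5)))
  expect_equal(f$axis_direction, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(f$length, 13.5, tolerance = 1e-12)

  # analytic alpha-helix: generating axis is the oracle
  ax <- unit3(c(0.3, -0.2, 1))
  pts <- ideal_helix_coords(20, axis_point = c(5, -3, 2), axis_direction = ax)
  f <- fit_helix_axis(pts)
  expect_lt(vec_angle(f$axis_direction, ax), 0.5)
  expect_equal(f$length, 28.5, tolerance = 0.5)

  expect_error(fit_helix_axis(cbind(0, 0, 0:2)), "degenerate")
  expect_error(fit_helix_axis(matrix(1, 6, 3)), "coincident")
})

test_that("axis fitting is invariant to rigid-body transforms", {
  set.seed(42)
  pts <- ideal_helix_coords(15, axis_direction = c(0, 0, 1))
  f0 <- fit_helix_axis(pts)
  for (k in 1:5) {
    R <- rotation_about(rnorm(3), runif(1, 0, 180))
    t <- rnorm(3, sd = 10)
    f1 <- fit_helix_axis(t(R %*% t(pts)) + rep(t, each = nrow(pts)))
    expect_equal(as.numeric(R %*% f0$axis_direction), f1$axis_direction,
                 tolerance = 1e-6)
    expect_equal(f0$length, f1$length, tolerance = 1e-6)
  }
})

make_seg <- function(point, dir, len = 20) {
  helix_segment(0L, "TM1", c(1L, 14L), point, dir, len)
}

test_that("crossing angle follows the declared handedness convention", {
  a <- make_seg(c(0, 0, 0), c(0, 0, 1))
  expect_equal(crossing_angle(a, make_seg(c(5, 0, 10), c(0, 0, 1))), 0)

  # a 35-degree right-handed rotation about the common normal reads -35
  w <- c(1, 0, 0)                       # common perpendicular
  v <- as.numeric(rotation_about(w, 35) %*% c(0, 0, 1))
  b <- make_seg(c(7, 0, 0), v)          # offset along +w
  expect_equal(crossing_angle(a, b), -35, tolerance = 1e-9)
  # symmetry in the arguments
  expect_equal(crossing_angle(a, b), crossing_angle(b, a), tolerance = 1e-12)
  # left-handed pair is positive
  v2 <- as.numeric(rotation_about(w, -35) %*% c(0, 0, 1))
  expect_equal(crossing_angle(a, make_seg(c(7, 0, 0), v2)), 35,
               tolerance = 1e-9)
})

test_that("crossing and inter-helix angles agree in magnitude", {
  set.seed(7)
  for (k in 1:10) {
    a <- make_seg(rnorm(3, sd = 5), unit3(rnorm(3)))
    b <- make_seg(rnorm(3, sd = 5), unit3(rnorm(3)))
    expect_equal(abs(crossing_angle(a, b)), interhelix_angle(a, b),
                 tolerance = 1e-9)
  }
})

test_that("inter-helix angle handles canonical cases", {
  a <- make_seg(c(0, 0, 0), c(0, 0, 1))
  expect_equal(interhelix_angle(a, make_seg(c(5, 0, 0), c(1, 0, 0))), 90)
  # constructed 147-degree opening angle
  v <- as.numeric(rotation_about(c(0, 1, 0), 147) %*% c(0, 0, 1))
  expect_equal(interhelix_angle(a, make_seg(c(3, 0, 0), v)), 147,
               tolerance = 1e-9)
  zl <- a; zl$length <- 0
  expect_error(interhelix_angle(zl, a), "zero-length")
})

test_that("closest approach measures finite-segment gaps", {
  a <- make_seg(c(0, 0, 10), c(0, 0, 1), 20)
  b <- make_seg(c(7, 0, 10), c(0, 0, 1), 20)
  expect_equal(closest_approach(a, b), 7, tolerance = 1e-9)

  # skew pair built from an explicit 12 A common perpendicular
  p <- make_seg(c(0, 0, 0), c(1, 0, 0), 30)
  q <- make_seg(c(0, 0, 12), unit3(c(0.2, 1, 0)), 30)
  expect_equal(closest_approach(p, q), 12, tolerance = 1e-9)

  # far-apart segments: endpoint distance, not the infinite-line distance
  r <- make_seg(c(100, 0, 0), c(0, 1, 0), 10)
  expect_gt(closest_approach(p, r), 80)
})
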