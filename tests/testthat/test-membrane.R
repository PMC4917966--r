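test_that("pressure profile satisfies its moment constraints", {
  patch <- bilayer_patch()
  p0 <- build_pressure_profile(patch, sigma_star = 0)
  expect_equal(profile_moment(p0), 0, tolerance = 1e-14)

  p3 <- build_pressure_profile(patch, sigma_star = 0.3)
  expect_equal(profile_moment(p3), -0.3, tolerance = 1e-12)
  # independent quadrature oracle on the piecewise profile
  q <- stats::integrate(function(z) pressure_at(p3, z),
                        -patch$rest_thickness / 2, patch$rest_thickness / 2,
                        subdivisions = 2000L, rel.tol = 1e-10)
  expect_equal(q$value / patch$rest_thickness, -0.3, tolerance = 1e-6)
  # smoothed evaluation preserves the moment (midpoint rule)
  z <- seq(-25, 25, length.out = 200001L)
  qs <- sum(pressure_at(p3, z, smooth = 1)) * (z[2L] - z[1L])
  expect_equal(qs / patch$rest_thickness, -0.3, tolerance = 1e-5)
})

test_that("band amplitudes scale affinely with the applied tension", {
  patch <- bilayer_patch()
  p1 <- build_pressure_profile(patch, sigma_star = 0.2)
  p2 <- build_pressure_profile(patch, sigma_star = 0.4)
  expect_equal(p2$bands$pressure, 2 * p1$bands$pressure, tolerance = 1e-12)
})

test_that("infeasible band geometry errors", {
  patch <- bilayer_patch()
  expect_error(build_pressure_profile(patch, 0.1, thickness = 15),
               "infeasible")
  expect_error(bilayer_patch(head_width = 10, interface_width = 10),
               "head_width")
})

test_that("thinning response is volume-conserving and monotone", {
  patch <- bilayer_patch()
  expect_equal(thinning_response(patch, 1)$thinning_percent, 0)
  th <- thinning_response(patch, 1 / 0.85)
  expect_equal(th$thinning_percent, 15, tolerance = 1e-9)
  expect_equal(patch$rest_thickness - th$h_far, 4.995, tolerance = 1e-9)
  # boundary layer: thickness at the protein closer to rest than far field
  expect_gt(th$thickness(patch$inner_radius), th$h_far)
  expect_equal(th$thickness(patch$outer_radius), th$h_far, tolerance = 1e-6)
  # monotone in areal stretch
  s <- seq(1, 1.4, by = 0.05)
  tp <- vapply(s, function(x) thinning_response(patch, x)$thinning_percent,
               numeric(1L))
  expect_true(all(diff(tp) > 0))
  expect_error(thinning_response(patch, 0.9), "compression")
})

test_that("membrane loads act on the right nodes with the right sign", {
  patch <- bilayer_patch()
  prof <- build_pressure_profile(patch, sigma_star = 0.3)
  # rod entirely below the membrane: zero load
  below <- cbind(10, 0, seq(-40, -25, length.out = 6))
  expect_equal(membrane_load_on_rod(prof, below, 10),
               matrix(0, 6, 3))
  # node in the tension-carrying interface band is pulled radially outward
  iface_z <- mean(unlist(prof$bands[prof$bands$name == "interface_bottom",
                                    c("zlo", "zhi")]))
  F <- membrane_load_on_rod(prof, cbind(12, 0, iface_z), 10)
  expect_gt(F[1, 1], 0)
  expect_equal(F[1, 2:3], c(0, 0))
  expect_error(membrane_load_on_rod(prof, cbind(NA, 0, 0), 1), "untagged")
})

test_that("a membrane-spanning rod carries the full line tension", {
  # vertical rod crossing all bands: the net lateral force equals the
  # band-wise quadrature of the profile over the rod width
  patch <- bilayer_patch()
  sigma <- 0.3
  prof <- build_pressure_profile(patch, sigma_star = sigma)
  n <- 2001L
  z <- seq(-patch$rest_thickness / 2, patch$rest_thickness / 2,
           length.out = n)
  dz <- z[2L] - z[1L]
  width <- 5
  F <- membrane_load_on_rod(prof, cbind(20, 0, z), dz * width)
  net <- sum(F[, 1L])
  oracle <- -sum(prof$bands$pressure * (prof$bands$zhi - prof$bands$zlo)) *
    width
  expect_equal(net, oracle, tolerance = 1e-3 * abs(oracle))
  # and that equals the line tension sigma* x h0 on the rod's width
  expect_equal(net, sigma * patch$rest_thickness * width,
               tolerance = 0.02 * net)
})
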