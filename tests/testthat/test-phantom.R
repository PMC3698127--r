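test_that("the phantom mask matches the analytic capsule volume", {
  ph <- make_vessel_phantom(seed = 1)       # radius 0.6 mm at 0.1 mm pitch
  r <- 0.6
  cl <- ph$centerline
  L <- sum(sqrt(rowSums((cl$points[-1, ] - cl$points[-nrow(cl$points), ])^2)))
  # 2D: strip of width 2r along the centreline plus two half-disc caps
  expected2d <- L * 2 * r + pi * r^2
  measured2d <- sum(ph$vessel_mask$values) * 0.1^2
  expect_equal(measured2d, expected2d, tolerance = 0.1)
  # 3D: tube of cross-section pi r^2 plus two hemispherical caps
  ph3 <- make_vessel_phantom(shape = c(64, 24, 64), voxel_pitch = 0.1,
                             arch_radius = 1.8, tube_radius = 0.6,
                             body_radius = 2.6, bone_radius = 0, seed = 1)
  cl3 <- ph3$centerline
  L3 <- sum(sqrt(rowSums((cl3$points[-1, ] - cl3$points[-nrow(cl3$points), ])^2)))
  expected3d <- L3 * pi * r^2 + 4 / 3 * pi * r^3
  measured3d <- sum(ph3$vessel_mask$values) * 0.1^3
  expect_equal(measured3d, expected3d, tolerance = 0.1)
})

test_that("the phantom is deterministic and validates its resolution limit", {
  a <- make_vessel_phantom(seed = 3)
  b <- make_vessel_phantom(seed = 3)
  expect_identical(a$attenuation$values, b$attenuation$values)
  expect_identical(a$vessel_mask$values, b$vessel_mask$values)
  expect_error(make_vessel_phantom(tube_radius = 0.15), "not resolvable")
})

test_that("a zero-length branch gives a single arch without bifurcation", {
  ph <- make_vessel_phantom(branch_length = 0, seed = 1)
  # arc length of a 180-degree arch of radius 5
  cl <- ph$centerline
  seg <- sqrt(rowSums((cl$points[-1, ] - cl$points[-nrow(cl$points), ])^2))
  expect_equal(sum(seg), pi * 5, tolerance = 0.01)
  # a branch extends the centerline
  phb <- make_vessel_phantom(branch_length = 2, seed = 1)
  clb <- phb$centerline
  segb <- sqrt(rowSums((clb$points[-1, ] - clb$points[-nrow(clb$points), ])^2))
  expect_equal(sum(segb), pi * 5 + 2, tolerance = 0.02)
})

test_that("the vessel mask is exactly the set of voxel centres inside the tube", {
  ph <- make_vessel_phantom(shape = c(96, 96), arch_radius = 2.5,
                            body_radius = 4, seed = 2)
  v <- ph$attenuation
  d <- dim(v$values)
  ax <- lapply(1:2, function(a) v$origin[a] + (seq_len(d[a]) - 0.5) * v$voxel_pitch)
  grid <- cbind(rep(ax[[1]], times = d[2]), rep(ax[[2]], each = d[1]))
  dist <- sparsect:::dist_to_polyline(grid, ph$centerline$points)
  expect_identical(array(dist <= ph$tube_radius, d), ph$vessel_mask$values)
})

test_that("noise-free simulation returns the exact line integrals", {
  ph <- small_phantom()
  g <- scan_geometry(n_views = 8, det_pitch = 0.35, det_count = 72)
  pr <- simulate_projections(ph, g, photons = Inf)
  expect_identical(pr$values, forward_project(ph$attenuation, g)$values)
})

test_that("noisy sinograms are unbiased around the noise-free projection", {
  ph <- small_phantom()
  g <- scan_geometry(n_views = 2, det_pitch = 0.35, det_count = 24)
  noisefree <- simulate_projections(ph, g, photons = Inf)$values
  I0 <- 1e4
  reps <- 400
  acc <- array(0, dim(noisefree))
  acc2 <- array(0, dim(noisefree))
  for (i in seq_len(reps)) {
    m <- simulate_projections(ph, g, photons = I0, seed = i)$values
    acc <- acc + m
    acc2 <- acc2 + m^2
  }
  mn <- acc / reps
  se <- sqrt(pmax(acc2 / reps - mn^2, 0) / reps)
  # within 4 standard errors almost everywhere (allowing the odd 1-in-16000)
  frac_bad <- mean(abs(mn - noisefree) > 4 * pmax(se, 1e-12))
  expect_lt(frac_bad, 0.005)
})

test_that("count clamping keeps log measurements finite and noise grows as photons shrink", {
  ph <- small_phantom()
  g <- scan_geometry(n_views = 4, det_pitch = 0.35, det_count = 48)
  m_low <- simulate_projections(ph, g, photons = 3, seed = 1)$values
  expect_true(all(is.finite(m_low)))
  noisefree <- simulate_projections(ph, g, photons = Inf)$values
  sds <- sapply(c(1e5, 1e3, 10), function(I0)
    sd(simulate_projections(ph, g, photons = I0, seed = 2)$values - noisefree))
  expect_true(all(diff(sds) > 0))
  expect_error(simulate_projections(ph, g, photons = 0), "positive")
})

test_that("phantom projections are reproducible under a fixed seed", {
  ph <- small_phantom()
  g <- scan_geometry(n_views = 4, det_pitch = 0.35, det_count = 48)
  a <- simulate_projections(ph, g, photons = 1e3, seed = 9)
  b <- simulate_projections(ph, g, photons = 1e3, seed = 9)
  expect_identical(a$values, b$values)
})
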