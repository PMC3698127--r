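test_that("VOI statistics use the sample standard deviation", {
  v <- volume_image(matrix(c(2, 2, 2, 9, 9, 9), 2, 3), 0.1)
  voi <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 2, 3)
  st <- voi_statistics(v, voi)
  expect_equal(st$mean, 2); expect_equal(st$sd, 0)
  expect_equal(st$min, 2); expect_equal(st$max, 2)

  v2 <- volume_image(matrix(c(1, 2, 3, 4, 5, 99), 2, 3), 0.1)
  voi2 <- matrix(c(rep(TRUE, 5), FALSE), 2, 3)
  st2 <- voi_statistics(v2, voi2)
  expect_equal(st2$mean, 3)
  expect_equal(st2$sd, sd(1:5))         # 1.5811...
  expect_equal(c(st2$min, st2$max), c(1, 5))

  v1 <- volume_image(matrix(7, 1, 1) + matrix(0, 1, 1), 0.1)
  st1 <- voi_statistics(v1, matrix(TRUE, 1, 1))
  expect_equal(c(st1$mean, st1$sd, st1$min, st1$max), c(7, 0, 7, 7))

  expect_error(voi_statistics(v, matrix(FALSE, 2, 3)), "empty")
})

test_that("thresholding selects the clamped 3-sigma interval inclusively", {
  vals <- matrix(c(0.9, 1, 2, 3, 4, 5, 5.0, 6), 2, 4)
  v <- volume_image(vals, 0.1)
  voi <- matrix(FALSE, 2, 4); voi[c(2, 3, 4, 5, 6)] <- TRUE   # values 1..5
  st <- voi_statistics(v, voi)
  m <- threshold_segment(v, st)
  # interval is [max(1, 3-3sd), min(5, 3+3sd)] = [1, 5]
  expect_identical(m$values, vals >= 1 & vals <= 5)
  expect_false(m$values[1, 1])   # 0.9 excluded
  expect_true(any(m$values[vals == 5]))  # bound inclusive

  stc <- voi_statistics(volume_image(matrix(2, 2, 2), 0.1), matrix(TRUE, 2, 2))
  mc <- threshold_segment(volume_image(matrix(c(2, 2.0001, 1.9999, 2), 2, 2), 0.1), stc)
  expect_identical(sum(mc$values), 2L)   # only exact value when sd = 0
})

test_that("erosion follows the outside-is-background minimum rule", {
  # isolated voxel disappears
  x <- array(FALSE, c(5, 5, 5)); x[3, 3, 3] <- TRUE
  expect_false(any(erode26(x)))
  # solid 3x3x3 cube leaves only its centre
  y <- array(FALSE, c(5, 5, 5)); y[2:4, 2:4, 2:4] <- TRUE
  ey <- erode26(y)
  expect_identical(which(ey), which(array(seq_len(125), c(5, 5, 5)) == 63L))
  # an all-true volume loses its border shell
  z <- array(TRUE, c(4, 4, 4))
  ez <- erode26(z)
  expect_identical(sum(ez), 8L)        # 2x2x2 core
  expect_true(all(which(ez, arr.ind = TRUE) >= 2))
})

test_that("dilation is the dual of erosion and opening recovers a convex block", {
  x <- array(FALSE, c(5, 5, 5)); x[3, 3, 3] <- TRUE
  dx <- dilate26(x)
  expect_identical(sum(dx), 27L)
  # clipped at borders
  xc <- array(FALSE, c(3, 3, 3)); xc[1, 1, 1] <- TRUE
  expect_identical(sum(dilate26(xc)), 8L)
  # opening of a solid 5^3 cube inside a 7^3 grid recovers it exactly
  y <- array(FALSE, c(7, 7, 7)); y[2:6, 2:6, 2:6] <- TRUE
  expect_identical(dilate26(erode26(y)), y)
  # empty stays empty
  expect_false(any(dilate26(array(FALSE, c(3, 3, 3)))))
})

test_that("region growing selects exactly the seeded 26-connected component", {
  x <- array(FALSE, c(8, 8, 1))
  x[2:3, 2:3, 1] <- TRUE          # blob A
  x[6:7, 6:7, 1] <- TRUE          # blob B
  seed <- array(FALSE, c(8, 8, 1)); seed[2, 2, 1] <- TRUE
  g <- region_grow(x, seed)
  expect_identical(sum(g), 4L)
  expect_true(all(which(g, arr.ind = TRUE)[, 1] <= 3))
  # candidate == seed is the identity
  expect_identical(region_grow(x, x), x)
  # diagonal touching counts as connected
  d <- matrix(FALSE, 4, 4); d[1, 1] <- TRUE; d[2, 2] <- TRUE
  sd_ <- matrix(FALSE, 4, 4); sd_[1, 1] <- TRUE
  expect_identical(sum(region_grow(d, sd_)), 2L)
  # disjoint seed errors
  s2 <- array(FALSE, c(8, 8, 1)); s2[5, 5, 1] <- TRUE
  expect_error(region_grow(x, s2), "does not intersect")
})

test_that("hole filling: literal mode is one OR-pass, topological mode closes cavities", {
  # single interior hole: both modes fill it
  x <- array(TRUE, c(3, 3, 3)); x[2, 2, 2] <- FALSE
  expect_true(all(fill_holes(x, "literal")))
  expect_true(all(fill_holes(x, "topological")))
  # empty mask stays empty
  expect_false(any(fill_holes(array(FALSE, c(3, 3, 3)), "literal")))
  expect_false(any(fill_holes(array(FALSE, c(3, 3, 3)), "topological")))
  # a wide cavity (3 voxels across) in a solid block: the single OR-pass
  # cannot reach the cavity centre, the flood fill can; the OR-pass also
  # inflates the outer boundary.  (A 2-voxel-wide cavity *is* closed by the
  # 26-neighbour OR, since every cavity voxel touches a wall diagonally.)
  y <- array(FALSE, c(9, 9, 9)); y[2:8, 2:8, 2:8] <- TRUE
  y[4:6, 4:6, 4:6] <- FALSE
  lit <- fill_holes(y, "literal")
  topo <- fill_holes(y, "topological")
  expect_false(lit[5, 5, 5])
  expect_true(all(topo[4:6, 4:6, 4:6]))
  expect_gt(sum(lit & !y), 27L)           # literal also adds a boundary shell
  expect_identical(sum(topo & !y), 27L)   # topological fills the cavity only
})

test_that("morphology invariants hold on random masks", {
  set.seed(99)
  for (i in 1:5) {
    x <- array(runif(6 * 6 * 6) < 0.4, c(6, 6, 6))
    e <- erode26(x); d <- dilate26(x)
    expect_true(all(!e | x))          # erode(m) subset of m
    expect_true(all(!x | d))          # m subset of dilate(m)
    if (any(x)) {
      seed <- array(FALSE, dim(x)); seed[which(x)[1]] <- TRUE
      g <- region_grow(x, seed)
      expect_true(all(!g | x))        # grown subset of candidate
    }
  }
})

test_that("the full chain segments the noise-free phantom almost perfectly", {
  ph <- make_vessel_phantom(seed = 1)
  voi <- phantom_seed_voi(ph)
  m <- segment_vessels(ph$attenuation, voi)
  cls <- classify_voxels(m, ph$vessel_mask)
  expect_gte(cls$tp_frac, 0.98)
  expect_lte(cls$fp_frac, 0.02)
  st <- attr(m, "stages")
  expect_named(st, c("threshold", "eroded", "grown", "dilated", "filled"))
  # determinism
  m2 <- segment_vessels(ph$attenuation, voi)
  expect_identical(m$values, m2$values)
})

test_that("growth stays within one intensity class and never crosses a strong edge", {
  set.seed(42)
  v <- matrix(0.02, 40, 40)
  v[, 21:40] <- 0.06                      # two flat regions, sharp edge
  v <- v + matrix(rnorm(1600, sd = 1e-4), 40, 40)
  voi <- matrix(FALSE, 40, 40); voi[18:22, 5:9] <- TRUE   # inside the low class
  m <- segment_vessels(volume_image(v, 0.1), voi)
  expect_false(any(m$values[, 23:40]))
})

test_that("stage order matters: dilating before growing bridges near-touching blobs", {
  # two blobs separated by a 2-voxel gap: the specified order keeps only the
  # seeded blob; dilating the threshold mask first would bridge the gap
  v <- matrix(0.02, 20, 20)
  v[4:9, 4:9] <- 0.06
  v[4:9, 12:17] <- 0.06
  vol <- volume_image(v, 0.1)
  voi <- matrix(FALSE, 20, 20); voi[6:7, 6:7] <- TRUE
  m <- segment_vessels(vol, voi)
  expect_false(any(m$values[, 12:17]))
  st <- voi_statistics(vol, voi)
  thr <- threshold_segment(vol, st)
  bridged <- region_grow(dilate26(thr), voi)
  expect_true(any(bridged$values[, 12:17]))
})

test_that("enlarging a seed VOI inside one intensity class never shrinks the mask", {
  ph <- make_vessel_phantom(seed = 4)
  voi_small <- phantom_seed_voi(ph, radius_mm = 0.2)
  voi_big <- phantom_seed_voi(ph, radius_mm = 0.4)
  m_small <- segment_vessels(ph$attenuation, voi_small)
  m_big <- segment_vessels(ph$attenuation, voi_big)
  expect_true(all(!m_small$values | m_big$values))
})
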