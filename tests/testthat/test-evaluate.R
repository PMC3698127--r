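test_that("voxel classification counts and conservation laws are exact", {
  ref <- matrix(c(TRUE, TRUE, FALSE), 1, 3)
  tst <- matrix(c(FALSE, TRUE, TRUE), 1, 3)
  cls <- classify_voxels(tst, ref)
  expect_identical(c(cls$tp, cls$fp, cls$fn), c(1L, 1L, 1L))

  expect_error(classify_voxels(matrix(TRUE, 2, 2), matrix(TRUE, 1, 4)), "shape")

  set.seed(2)
  for (i in 1:5) {
    a <- matrix(runif(100) < 0.5, 10, 10)
    b <- matrix(runif(100) < 0.3, 10, 10)
    cls <- classify_voxels(a, b)
    expect_identical(cls$tp + cls$fn, sum(b))
    expect_identical(cls$tp + cls$fp, sum(a))
  }

  same <- classify_voxels(ref, ref)
  expect_identical(c(same$fp, same$fn), c(0L, 0L))
  expect_identical(same$tp, sum(ref))
  none <- classify_voxels(ref & FALSE, ref)
  expect_identical(c(none$tp, none$fn), c(0L, sum(ref)))
})

test_that("point matching is nearest-neighbour with low-index tie breaking", {
  p <- cbind(c(0, 1, 2), c(0, 0, 0))
  cl <- centerline(p, cbind(1, c(0, 0, 0)), c(1, 1, 1))
  m <- match_points(cl, cl)
  expect_identical(m$ref_index, 1:3)
  expect_equal(m$distance, rep(0, 3))

  shifted <- centerline(sweep(p, 2, c(0.1, 0), `+`), cbind(1, c(0, 0, 0)),
                        c(1, 1, 1))
  ms <- match_points(shifted, cl)
  expect_equal(ms$distance, rep(0.1, 3), tolerance = 1e-12)

  # equidistant tie: reference points at y = +1 and y = -1
  ref2 <- centerline(cbind(c(0, 0), c(1, -1)), cbind(c(1, 1), c(0, 0)), c(1, 1))
  q <- centerline(cbind(c(0, 5), c(0, 0)), cbind(c(1, 1), c(0, 0)), c(1, 1))
  mt <- match_points(q, ref2)
  expect_identical(mt$ref_index[1], 1L)
})

test_that("diameter error and centerline distance behave as metrics on matched pairs", {
  p <- cbind(seq(0, 2, by = 0.5), 0)
  t <- cbind(1, rep(0, 5))
  ref <- centerline(p, t, rep(1.0, 5))
  same <- centerline(p, t, rep(1.0, 5))
  expect_equal(relative_diameter_error(same, ref), 0)
  expect_equal(centerline_distance(same, ref), 0)

  twoup <- centerline(p[1:2, ], t[1:2, ], c(1.0, 1.1))
  expect_equal(relative_diameter_error(twoup, ref), 5)   # mean of 0% and 10%

  shifted <- centerline(sweep(p, 2, c(0, 0.1), `+`), t, rep(1.0, 5))
  expect_equal(centerline_distance(shifted, ref), 0.1, tolerance = 1e-12)
  # translation moves the distance but not the diameter error
  expect_equal(relative_diameter_error(shifted, ref), 0)

  # brute-force check on a hand-built 3-point case
  a <- centerline(cbind(c(0, 1, 2), c(0.3, -0.2, 0.1)),
                  cbind(1, c(0, 0, 0)), c(1.1, 0.9, 1.2))
  d_brute <- mean(sapply(1:3, function(i)
    min(sqrt(rowSums(sweep(ref$points, 2, a$points[i, ])^2)))))
  expect_equal(centerline_distance(a, ref), d_brute)
})

test_that("the printed diameter-difference arithmetic reproduces 164 um", {
  expect_equal(diameter_difference_um(13.66, 1.2), 164, tolerance = 0.005)
  expect_equal(diameter_difference_um(13.7, 1.2), 164.4)
  expect_equal(diameter_difference_um(0), 0)
})

test_that("condition comparison runs a two-tailed t-test with degenerate-case handling", {
  x <- c(5.1, 6.5, 13.7, 7.2)
  expect_warning(r0 <- compare_conditions(x, x), "zero")
  expect_equal(r0$p_value, 1)
  expect_false(r0$significant)

  set.seed(7)
  a <- rnorm(50, mean = 1); b <- rnorm(50, mean = 0)
  r <- compare_conditions(a, b, paired = FALSE)
  expect_lt(r$p_value, 0.05)
  expect_true(r$significant)
  # two-tailed symmetry
  r_sw <- compare_conditions(b, a, paired = FALSE)
  expect_equal(r$p_value, r_sw$p_value)

  # paired vs unpaired give the t.test results
  y <- x + c(0.5, -0.2, 0.1, 0.4)
  rp <- compare_conditions(x, y, paired = TRUE)
  expect_equal(rp$p_value, t.test(x, y, paired = TRUE)$p.value)

  expect_error(compare_conditions(1, c(1, 2)), "at least 2")
})
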