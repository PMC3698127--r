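test_that("stopping metric is the percent relative L2 change", {
  x <- matrix(runif(16), 4, 4)
  expect_equal(stop_metric(x, x), 0)
  expect_equal(stop_metric(x, 1.01 * x), 100 * 0.01 / 1.01, tolerance = 1e-10)
  # invariant to a common scale factor
  expect_equal(stop_metric(2 * x, 2 * 1.01 * x), stop_metric(x, 1.01 * x))
  expect_error(stop_metric(x, 0 * x), "all-zero")
  expect_error(stop_metric(x, matrix(1, 2, 8)), "same shape")
})

test_that("an identity system converges to the data in one iteration", {
  set.seed(10)
  m <- runif(9)
  r <- isra_solve(diag(9), m, x0 = rep(1, 9),
                  cfg = recon_config(max_iterations = 1))
  expect_identical(as.numeric(r$volume), m)
})

test_that("matched-system ISRA matches a nonnegative least-squares oracle", {
  set.seed(12)
  A <- matrix(runif(12 * 8), 12, 8)
  m <- as.numeric(A %*% runif(8) + 0.1 * runif(12))
  r <- isra_solve(A, m, cfg = recon_config(max_iterations = 5000,
                                           stop_threshold = 1e-8))
  x_oracle <- nnls_oracle(A, m)
  f <- function(x) sum((A %*% x - m)^2)
  expect_lt((f(r$volume) - f(x_oracle)) / f(x_oracle), 1e-3)
  # matched-pair monotonicity of the data-fit objective
  expect_true(all(diff(r$trace$data_fit) <= 1e-10))
  # nonnegativity of the limit
  expect_true(all(r$volume >= 0))
})

test_that("a voxel with zero back-projected data is driven to zero and stays there", {
  A <- cbind(c(1, 1, 0), c(0, 0, 1))
  m <- c(1, 1, 0)       # A^T m = (2, 0): voxel 2 has no support in the data
  r <- isra_solve(A, m, x0 = c(1, 1), cfg = recon_config(max_iterations = 10,
                                                         stop_threshold = 1e-12))
  expect_equal(as.numeric(r$volume)[2], 0)
  expect_gt(as.numeric(r$volume)[1], 0)
})

test_that("ISRA rejects invalid starts and degenerate data", {
  A <- diag(4)
  expect_error(isra_solve(A, rep(1, 4), x0 = c(1, 1, 0, 1)), "strictly positive")
  expect_error(isra_solve(A, rep(0, 4)), "degenerate")
})

test_that("negative sinogram entries are clipped and counted", {
  A <- diag(4)
  r <- isra_solve(A, c(1, -0.01, 2, 3), x0 = rep(1, 4),
                  cfg = recon_config(max_iterations = 3, stop_threshold = 1e-12))
  expect_identical(r$n_negative_clipped, 1L)
  expect_true(all(as.numeric(r$volume) >= 0))
})

test_that("lambda = 0 reproduces ISRA iterate-for-iterate", {
  ph <- small_phantom()
  g <- scan_geometry(n_views = 16, det_pitch = 0.35, det_count = 72)
  pr <- simulate_projections(ph, g, photons = 1e4, seed = 7)
  grid <- volume_image(matrix(0, 64, 64), 0.1)
  cfg <- recon_config(max_iterations = 5, stop_threshold = 1e-12)
  r0 <- isra(pr, cfg = cfg, vol_template = grid)
  rt <- isra_tv(pr, cfg = cfg, vol_template = grid, lambda = 0)
  expect_identical(r0$volume$values, rt$volume$values)
  expect_identical(r0$trace$stop_metric, rt$trace$stop_metric)
})

test_that("TV regularization lowers the TV energy of a noisy sparse-view reconstruction", {
  ph <- small_phantom()
  g <- scan_geometry(n_views = 32, det_pitch = 0.35, det_count = 72)
  pr <- simulate_projections(ph, g, photons = 1e4, seed = 7)
  grid <- volume_image(matrix(0, 64, 64), 0.1)
  cfg <- recon_config(max_iterations = 40, stop_threshold = 1e-9)
  ri <- isra(pr, cfg = cfg, vol_template = grid)
  rt <- isra_tv(pr, cfg = cfg, vol_template = grid)   # lambda 0.001 default
  expect_identical(ri$iterations, rt$iterations)      # equal iteration counts
  delta <- ri$tv_delta
  expect_lt(tv_energy(rt$volume, delta), tv_energy(ri$volume, delta))
  expect_true(all(ri$volume$values >= 0))
  expect_true(all(rt$volume$values >= 0))
  expect_identical(sum(rt$trace$n_clamped), 0L)
})

test_that("large penalties trip the one-step-late denominator clamp", {
  # the OSL modification carries no positivity guarantee: for large lambda
  # denominators go nonpositive and are clamped (and counted), rather than
  # the iteration converging to a flat image
  ph <- small_phantom()
  g <- scan_geometry(n_views = 16, det_pitch = 0.35, det_count = 72)
  pr <- simulate_projections(ph, g, photons = 1e4, seed = 7)
  grid <- volume_image(matrix(0, 64, 64), 0.1)
  r <- isra_tv(pr, cfg = recon_config(max_iterations = 15, stop_threshold = 1e-12),
               vol_template = grid, lambda = 50)
  expect_gt(sum(r$trace$n_clamped), 0)
  expect_true(all(r$volume$values >= 0))
})

test_that("the measured sinogram is read exactly once per reconstruction", {
  counter <- new.env()
  counter$values <- 0L
  assign("$.spy_proj", function(x, name) {
    if (name == "values") {
      e <- attr(x, "counter")
      e$values <- e$values + 1L
    }
    attr(x, "real")[[name]]
  }, envir = globalenv())
  withr::defer(rm("$.spy_proj", envir = globalenv()))
  ph <- small_phantom()
  g <- scan_geometry(n_views = 8, det_pitch = 0.35, det_count = 72)
  pr <- simulate_projections(ph, g, photons = Inf)
  spy <- structure(list(), class = c("spy_proj", "projection_data"))
  attr(spy, "real") <- pr
  attr(spy, "counter") <- counter
  r <- isra(spy, cfg = recon_config(max_iterations = 4, stop_threshold = 1e-12),
            vol_template = volume_image(matrix(0, 32, 32), 0.2))
  expect_identical(counter$values, 1L)
  expect_identical(r$iterations, 4L)
})

test_that("the convergence trace records the configured quantities", {
  A <- diag(6)
  m <- c(1, 2, 3, 4, 5, 6)
  r <- isra_solve(A, m, x0 = rep(1, 6),
                  cfg = recon_config(max_iterations = 8, stop_threshold = 1e-12))
  tr <- r$trace
  expect_true(all(c("iteration", "stop_metric", "data_fit", "tv_energy",
                    "n_clamped") %in% names(tr)))
  expect_lte(nrow(tr), 8)
  expect_true(all(tr$stop_metric >= 0))
  # identity system: converged after the first update, so the metric
  # collapses immediately afterwards
  expect_equal(tr$data_fit[2], 0, tolerance = 1e-20)
})
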