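#' Smoothed total-variation energy
#'
#' The regularization energy used by the one-step-late ISRA-TV update:
#' isotropic total variation with forward differences, replicate
#' (zero-gradient) boundary handling, and a small smoothing constant `delta`
#' added inside the square root to remove the non-differentiability at zero
#' gradient:
#' \deqn{U(x) = \sum_j \sqrt{\sum_a (x_{j+e_a} - x_j)^2 + \delta^2}.}
#' For a constant image `U = N * delta`; adding a constant to the image
#' leaves `U` unchanged.
#'
#' @param vol a [volume_image()], or a numeric vector/matrix/array.
#' @param delta smoothing constant, must be positive.
#' @return A finite nonnegative scalar.
#' @seealso [tv_gradient()]
#' @export
tv_energy <- function(vol, delta) {
  x <- tv_values(vol)
  stopifnot(is.numeric(delta), length(delta) == 1, delta > 0)
  ss <- 0
  for (a in seq_along(dim(x)))
    ss <- ss + fwd_diff(x, a)^2
  sum(sqrt(ss + delta^2))
}

#' Analytic gradient of the smoothed total-variation energy
#'
#' Exact partial derivatives of [tv_energy()] under the same discretization
#' (forward differences, replicate boundary).  Because the energy is
#' invariant to adding a constant, the gradient sums to zero over the grid
#' (up to floating point).
#'
#' @inheritParams tv_energy
#' @return An object matching the input shape: a [volume_image()] if `vol`
#'   is one, otherwise an array.
#' @export
tv_gradient <- function(vol, delta) {
  x <- tv_values(vol)
  stopifnot(is.numeric(delta), length(delta) == 1, delta > 0)
  nd <- length(dim(x))
  diffs <- lapply(seq_len(nd), function(a) fwd_diff(x, a))
  w <- Reduce(`+`, lapply(diffs, function(d) d^2)) + delta^2
  w <- sqrt(w)
  g <- array(0, dim(x))
  for (a in seq_len(nd)) {
    r <- diffs[[a]] / w
    g <- g - r + axis_shift_down(r, a)
  }
  if (inherits(vol, "volume_image"))
    volume_image(g, voxel_pitch = vol$voxel_pitch, origin = vol$origin)
  else g
}

# Coerce TV input to an array (vectors become 1-column "arrays" of dim n).
tv_values <- function(vol) {
  x <- if (inherits(vol, "volume_image")) vol$values else vol
  if (is.null(dim(x))) dim(x) <- length(x)
  if (!is.numeric(x)) stop("TV input must be numeric", call. = FALSE)
  x
}

# Forward difference along one axis, zero at the trailing boundary
# (replicate/zero-gradient convention).
fwd_diff <- function(x, axis) {
  axis_shift_up(x, axis) - x
}

# Shift an array by one index along `axis`, pulling the next element in and
# padding the freed trailing slice with the boundary value itself (so the
# forward difference there is zero).
axis_shift_up <- function(x, axis) {
  d <- dim(x)
  n <- d[axis]
  idx <- rep(list(quote(expr = )), length(d))
  idx[[axis]] <- c(seq_len(n - 1L) + 1L, n)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Shift values toward higher indices along `axis`, padding zeros in front.
axis_shift_down <- function(x, axis) {
  d <- dim(x)
  n <- d[axis]
  idx <- rep(list(quote(expr = )), length(d))
  idx[[axis]] <- c(1L, seq_len(n - 1L))
  out <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  first <- rep(list(quote(expr = )), length(d))
  first[[axis]] <- 1L
  do.call(`[<-`, c(list(out), first, list(value = 0)))
}
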