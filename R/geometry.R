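#' Scan geometry for a circular-trajectory CT acquisition
#'
#' Describes a fan-beam (2D) or cone-beam (3D) acquisition over a circular
#' source trajectory: source-to-axis and source-to-detector distances, a flat
#' detector, and an ordered set of view angles.  The defaults follow a
#' preclinical in vivo protocol: 2048 uniformly spaced views over 360 degrees
#' at 3.5x geometric magnification.  Absolute distances are chosen as
#' SAD = 50 mm and SDD = 175 mm; only their ratio (the magnification) enters
#' any reported metric.
#'
#' @param mode `"fan2d"` (single-row fan beam, 2D slice) or `"cone3d"`
#'   (multi-row flat-panel cone beam).
#' @param sad source-to-rotation-axis distance in mm.
#' @param sdd source-to-detector distance in mm; `sdd/sad` is the geometric
#'   magnification and must exceed 1.
#' @param det_pitch detector pixel pitch in mm (isotropic; rows use the same
#'   pitch in cone-beam mode).
#' @param det_count number of detector pixels per row.
#' @param det_rows number of detector rows (cone-beam mode only).
#' @param n_views number of uniformly spaced views over 360 degrees; ignored
#'   when `angles` is given.
#' @param angles optional explicit angle vector (radians, strictly increasing,
#'   all in `[0, 2*pi)`).
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry(n_views = 8, det_count = 32)
#' magnification(g)
#' @export
scan_geometry <- function(mode = c("fan2d", "cone3d"),
                          sad = 50, sdd = 175,
                          det_pitch = 0.35, det_count = 338L,
                          det_rows = NULL,
                          n_views = 2048L, angles = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(sad) || !is.numeric(sdd) || sad <= 0 || sdd <= 0)
    stop("source-axis and source-detector distances must be positive", call. = FALSE)
  if (sdd <= sad)
    stop("magnification sdd/sad must exceed 1", call. = FALSE)
  if (det_count < 1) stop("det_count must be >= 1", call. = FALSE)
  if (is.null(angles)) {
    n_views <- as.integer(n_views)
    if (is.na(n_views) || n_views < 1)
      stop("n_views must be a positive integer", call. = FALSE)
    angles <- 2 * pi * (seq_len(n_views) - 1L) / n_views
  } else {
    angles <- as.numeric(angles)
    if (length(angles) < 1 || anyNA(angles))
      stop("angles must be a non-empty numeric vector", call. = FALSE)
    if (any(angles < 0 | angles >= 2 * pi))
      stop("angles must lie in [0, 2*pi)", call. = FALSE)
    if (length(angles) > 1 && any(diff(angles) <= 0))
      stop("angles must be strictly increasing", call. = FALSE)
  }
  if (mode == "cone3d") {
    if (is.null(det_rows)) det_rows <- det_count
    det_rows <- as.integer(det_rows)
    if (det_rows < 1) stop("det_rows must be >= 1", call. = FALSE)
  } else {
    det_rows <- NULL
  }
  structure(
    list(mode = mode, sad = sad, sdd = sdd,
         det_pitch = det_pitch, det_count = as.integer(det_count),
         det_rows = det_rows, angles = angles),
    class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %s\n", x$mode))
  cat(sprintf("  SAD %.3g mm, SDD %.3g mm (magnification %.3g)\n",
              x$sad, x$sdd, magnification(x)))
  cat(sprintf("  detector: %d px @ %.3g mm%s (FOV %.4g mm at isocentre)\n",
              x$det_count, x$det_pitch,
              if (!is.null(x$det_rows)) sprintf(" x %d rows", x$det_rows) else "",
              x$det_count * x$det_pitch / magnification(x)))
  cat(sprintf("  %d views over [%.4g, %.4g] rad\n",
              length(x$angles), min(x$angles), max(x$angles)))
  invisible(x)
}

#' Geometric magnification of a scan geometry
#'
#' @param geom a [scan_geometry()].
#' @return `sdd / sad`.
#' @export
magnification <- function(geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  geom$sdd / geom$sad
}

#' Log-transformed projection data (sinogram) bound to a scan geometry
#'
#' Values are dimensionless line integrals `-log(I/I0)`, arranged as
#' `views x detector` (fan-beam) or `views x rows x detector` (cone-beam).
#' Negative entries are admitted only within `neg_tol`, a noise allowance
#' fixed at creation (photon noise can push a log-transformed measurement
#' slightly below zero).
#'
#' @param values numeric matrix or 3D array of line integrals.
#' @param geometry the [scan_geometry()] the data were measured under.
#' @param photon_budget optional photons per detector pixel used when the
#'   data were simulated; `Inf` means noise-free.
#' @param neg_tol largest admissible magnitude of a negative value.
#' @return An object of class `projection_data`.
#' @export
projection_data <- function(values, geometry, photon_budget = NULL,
                            neg_tol = 0) {
  stopifnot(inherits(geometry, "scan_geometry"))
  values <- as.array(values)
  nd <- length(dim(values))
  if (geometry$mode == "fan2d" && nd != 2)
    stop("fan2d projection data must be a views x detector matrix", call. = FALSE)
  if (geometry$mode == "cone3d" && nd != 3)
    stop("cone3d projection data must be a views x rows x detector array", call. = FALSE)
  if (dim(values)[1] != length(geometry$angles))
    stop("first dimension must equal the number of view angles", call. = FALSE)
  if (geometry$mode == "fan2d" && dim(values)[2] != geometry$det_count)
    stop("detector dimension does not match the geometry", call. = FALSE)
  if (geometry$mode == "cone3d" &&
      (dim(values)[2] != geometry$det_rows || dim(values)[3] != geometry$det_count))
    stop("detector dimensions do not match the geometry", call. = FALSE)
  if (!all(is.finite(values)))
    stop("projection values must be finite", call. = FALSE)
  if (any(values < -abs(neg_tol)))
    stop("negative line integrals exceed the configured noise tolerance", call. = FALSE)
  structure(
    list(values = values, geometry = geometry,
         photon_budget = photon_budget, neg_tol = neg_tol),
    class = "projection_data")
}

#' @export
print.projection_data <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<projection_data> %s, %s [views%s x det]\n",
              x$geometry$mode, paste(d, collapse = " x "),
              if (length(d) == 3) " x rows" else ""))
  cat(sprintf("  range [%.4g, %.4g]%s\n", min(x$values), max(x$values),
              if (!is.null(x$photon_budget))
                sprintf(", simulated at %.3g photons/pixel", x$photon_budget)
              else ""))
  invisible(x)
}

#' Scalar attenuation volume on a regular grid
#'
#' A 2D or 3D grid of linear attenuation coefficients (1/mm) with a physical
#' voxel pitch and the mm coordinates of the grid corner.  Voxel centres lie
#' at `origin + (index + 0.5) * voxel_pitch` with 0-based indices; the default
#' origin centres the grid on the rotation axis.
#'
#' @param values numeric matrix (fan-beam slices) or 3D array.
#' @param voxel_pitch voxel edge length in mm (default 0.1 mm).
#' @param origin numeric vector of corner coordinates in mm, one per axis;
#'   default centres the volume at the isocentre.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, voxel_pitch = 0.1, origin = NULL) {
  values <- as.array(values)
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L))
    stop("volume must be 2D or 3D", call. = FALSE)
  if (!is.numeric(voxel_pitch) || voxel_pitch <= 0)
    stop("voxel_pitch must be positive", call. = FALSE)
  if (is.null(origin)) origin <- -dim(values) * voxel_pitch / 2
  if (length(origin) != nd)
    stop("origin must have one coordinate per axis", call. = FALSE)
  structure(
    list(values = values, voxel_pitch = voxel_pitch, origin = as.numeric(origin)),
    class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s @ %.3g mm pitch, origin (%s) mm\n",
              paste(dim(x$values), collapse = " x "), x$voxel_pitch,
              paste(sprintf("%.3g", x$origin), collapse = ", ")))
  cat(sprintf("  attenuation range [%.4g, %.4g] 1/mm\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.volume_image <- function(x, slice = NULL, ...) {
  v <- x$values
  if (length(dim(v)) == 3) {
    if (is.null(slice)) slice <- ceiling(dim(v)[3] / 2)
    v <- v[, , slice]
  }
  graphics::image(seq_len(nrow(v)), seq_len(ncol(v)), v, asp = 1,
                  col = grDevices::gray.colors(256), xlab = "x", ylab = "y", ...)
  invisible(x)
}

#' Binary mask aligned to a volume grid
#'
#' @param values logical matrix/array (anything coercible with `as.logical`).
#' @param voxel_pitch,origin grid metadata, as in [volume_image()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, voxel_pitch = 0.1, origin = NULL) {
  values <- as.array(values)
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask values must not contain NA", call. = FALSE)
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L)) stop("mask must be 2D or 3D", call. = FALSE)
  if (is.null(origin)) origin <- -dim(values) * voxel_pitch / 2
  structure(
    list(values = values, voxel_pitch = voxel_pitch, origin = as.numeric(origin)),
    class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s @ %.3g mm pitch, %d foreground voxels (%.2f%%)\n",
              paste(dim(x$values), collapse = " x "), x$voxel_pitch,
              sum(x$values), 100 * mean(x$values)))
  invisible(x)
}

# Internal: coerce mask-like input to a logical array.
mask_values <- function(m) {
  if (inherits(m, "binary_mask")) return(m$values)
  v <- as.array(m)
  storage.mode(v) <- "logical"
  v
}

#' Retrospective projection-view subsampling
#'
#' Emulates a sparser (lower-dose, faster) acquisition by keeping only every
#' `n`-th view of a measured dataset: views at indices 0, n, 2n, ...
#' (0-based), so a 2048-view scan subsampled with `n = 8` yields 256
#' uniformly spaced views.  The attached geometry's angle set is subsampled
#' identically.
#'
#' @param proj a [projection_data()] object.
#' @param n positive integer subsampling factor; must divide the view count.
#' @return A [projection_data()] object with `length(angles)/n` views.
#' @export
subsample_views <- function(proj, n) {
  stopifnot(inherits(proj, "projection_data"))
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be a positive integer", call. = FALSE)
  nv <- length(proj$geometry$angles)
  if (nv %% n != 0)
    stop(sprintf("n = %d does not divide the view count %d", n, nv), call. = FALSE)
  keep <- seq(1L, nv, by = n)
  g <- proj$geometry
  g$angles <- g$angles[keep]
  vals <- if (g$mode == "fan2d") proj$values[keep, , drop = FALSE]
          else proj$values[keep, , , drop = FALSE]
  projection_data(vals, g, photon_budget = proj$photon_budget,
                  neg_tol = proj$neg_tol)
}
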