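#' Forward projection (pixel-driven ray casting)
#'
#' Computes line integrals of an attenuation volume for every (view,
#' detector pixel) pair of a scan geometry.  Each detector pixel is connected
#' to the X-ray source and the volume is sampled along that ray with linear
#' (bi/trilinear) interpolation at a step of half the voxel pitch; the sum of
#' samples times the step length approximates the path integral.  The
#' operator is linear in the volume and a zero volume maps to a zero
#' sinogram.  The focal spot is treated as a point.
#'
#' @param vol a [volume_image()] whose dimensionality matches `geom$mode`.
#' @param geom a [scan_geometry()].
#' @return A [projection_data()] object of noise-free line integrals.
#' @seealso [back_project()], [build_system_matrix()]
#' @export
forward_project <- function(vol, geom) {
  stopifnot(inherits(vol, "volume_image"), inherits(geom, "scan_geometry"))
  nd <- length(dim(vol$values))
  if (geom$mode == "fan2d") {
    if (nd != 2) stop("fan2d geometry requires a 2D volume", call. = FALSE)
    m <- .cpp_forward_fan2d(vol$values, vol$voxel_pitch,
                            vol$origin[1], vol$origin[2],
                            geom$angles, geom$sad, geom$sdd,
                            geom$det_pitch, geom$det_count)
  } else {
    if (nd != 3) stop("cone3d geometry requires a 3D volume", call. = FALSE)
    m <- .cpp_forward_cone3d(vol$values, dim(vol$values), vol$voxel_pitch,
                             vol$origin[1], vol$origin[2], vol$origin[3],
                             geom$angles, geom$sad, geom$sdd,
                             geom$det_pitch, geom$det_count, geom$det_rows)
  }
  projection_data(m, geom, photon_budget = Inf)
}

#' Back projection (voxel-driven accumulation)
#'
#' For every voxel and every view, the voxel centre is connected to the
#' source, the intersection of that ray with the detector is computed, and
#' the linearly interpolated detector value is accumulated.  The operator is
#' linear and maps a zero sinogram to a zero volume.  Note that this
#' voxel-driven back projector is deliberately *not* the exact transpose of
#' the pixel-driven [forward_project()]; an exactly matched pair is available
#' through [build_system_matrix()].
#'
#' @param proj a [projection_data()].
#' @param vol_template a [volume_image()] (or `NULL`) fixing the output grid;
#'   by default a centred grid with 0.1 mm pitch covering the field of view.
#' @return A [volume_image()].
#' @export
back_project <- function(proj, vol_template = NULL) {
  stopifnot(inherits(proj, "projection_data"))
  geom <- proj$geometry
  if (is.null(vol_template)) vol_template <- default_grid(geom)
  pitch <- vol_template$voxel_pitch
  dm <- dim(vol_template$values)
  if (geom$mode == "fan2d") {
    out <- .cpp_back_fan2d(proj$values, dm[1], dm[2], pitch,
                           vol_template$origin[1], vol_template$origin[2],
                           geom$angles, geom$sad, geom$sdd, geom$det_pitch)
  } else {
    out <- .cpp_back_cone3d(proj$values, dim(proj$values), dm, pitch,
                            vol_template$origin[1], vol_template$origin[2],
                            vol_template$origin[3],
                            geom$angles, geom$sad, geom$sdd, geom$det_pitch)
  }
  volume_image(out, voxel_pitch = pitch, origin = vol_template$origin)
}

# Default reconstruction grid: isotropic 0.1 mm pitch covering the detector
# field of view at the isocentre, centred on the rotation axis.
default_grid <- function(geom, voxel_pitch = 0.1) {
  fov <- geom$det_count * geom$det_pitch / magnification(geom)
  n <- as.integer(ceiling(fov / voxel_pitch))
  if (geom$mode == "fan2d") {
    volume_image(matrix(0, n, n), voxel_pitch = voxel_pitch)
  } else {
    fovz <- geom$det_rows * geom$det_pitch / magnification(geom)
    nz <- as.integer(ceiling(fovz / voxel_pitch))
    volume_image(array(0, c(n, n, nz)), voxel_pitch = voxel_pitch)
  }
}

#' Explicit dense system matrix (small-instance oracle)
#'
#' Builds the dense matrix `A` with `A[i, j]` the contribution of voxel `j`
#' to detector measurement `i` under exactly the same pixel-driven sampling
#' model as [forward_project()], so that `A %*% as.vector(vol)` reproduces
#' the forward projection to floating-point accuracy.  Row order matches
#' `as.vector()` of the projection array; column order matches `as.vector()`
#' of the volume array.  The matrix is dense and intended for small
#' instances (verification, matched-pair reconstruction experiments); an
#' element cap guards against accidental huge allocations.
#'
#' @param geom a [scan_geometry()].
#' @param vol_template a [volume_image()] fixing grid shape, pitch, origin.
#' @param model `"ray"` (the physical sampling model) or `"identity"` (a
#'   diagnostic mode: one ray per voxel with unit weight, i.e. the identity
#'   matrix, useful for algorithm contract tests).
#' @param max_elements cap on `nrow * ncol` (default 2^24).
#' @return A dense numeric matrix of nonnegative weights with attributes
#'   `geometry` and `vol_template`.
#' @export
build_system_matrix <- function(geom, vol_template, model = c("ray", "identity"),
                                max_elements = 2^24) {
  stopifnot(inherits(geom, "scan_geometry"), inherits(vol_template, "volume_image"))
  model <- match.arg(model)
  nvox <- length(vol_template$values)
  if (model == "identity") {
    A <- diag(nvox)
  } else {
    nray <- length(geom$angles) * geom$det_count *
      (if (geom$mode == "cone3d") geom$det_rows else 1L)
    if (as.double(nray) * nvox > max_elements)
      stop(sprintf("system matrix would hold %.3g elements (cap %.3g); the dense oracle is for small instances only",
                   as.double(nray) * nvox, max_elements), call. = FALSE)
    dm <- dim(vol_template$values)
    if (geom$mode == "fan2d") {
      A <- .cpp_sysmat_fan2d(dm[1], dm[2], vol_template$voxel_pitch,
                             vol_template$origin[1], vol_template$origin[2],
                             geom$angles, geom$sad, geom$sdd,
                             geom$det_pitch, geom$det_count)
    } else {
      A <- .cpp_sysmat_cone3d(dm, vol_template$voxel_pitch,
                              vol_template$origin[1], vol_template$origin[2],
                              vol_template$origin[3],
                              geom$angles, geom$sad, geom$sdd,
                              geom$det_pitch, geom$det_count, geom$det_rows)
    }
  }
  attr(A, "geometry") <- geom
  attr(A, "vol_template") <- vol_template
  A
}
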