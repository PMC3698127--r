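#' Synthetic contrast-enhanced vessel phantom
#'
#' Builds an analytic stand-in for a contrast-enhanced murine aortic arch:
#' a curved tube (an arc in 2D, an arch-shaped tube bent in the x-z plane in
#' 3D) of constant diameter embedded in a soft-tissue body, with an optional
#' straight descending branch continuing from one end of the arch and an
#' optional bone-like insert.  The tube centreline is known in closed form
#' and is returned sampled at sub-voxel spacing together with the per-point
#' true diameter, so segmentation and centerline algorithms can be scored
#' against exact ground truth.  The voxel mask contains exactly the voxels
#' whose centre lies inside the analytic tube.
#'
#' Attenuation defaults (background 0.02, vessel 0.06, bone 0.10 per mm) are
#' plausible contrast levels for iodine-enhanced soft tissue imaging, not
#' measured values.
#'
#' @param shape integer vector of grid dimensions: length 2 (fan-beam slice)
#'   or 3 (volume).  Default `c(192, 192)`.
#' @param voxel_pitch voxel size in mm (default 0.1).
#' @param arch_radius radius of the arch centreline in mm (default 5).
#' @param tube_radius vessel lumen radius in mm (default 0.6, i.e. a 1.2 mm
#'   diameter, the mean aortic diameter of the reference segmentations).
#' @param arch_span_deg angular span of the arch in degrees (default 180).
#' @param branch_length length in mm of an optional straight branch
#'   continuing tangentially from the end of the arch (default 0: none).
#' @param body_radius radius of the circular soft-tissue body in mm.
#' @param mu_background,mu_vessel,mu_bone attenuation levels in 1/mm;
#'   must satisfy `mu_background < mu_vessel`.
#' @param bone_radius radius of the bone insert in mm; `0` disables it.
#' @param centerline_spacing spacing of the sampled truth centreline in mm
#'   (default half a voxel; must be at most one voxel).
#' @param seed integer recorded with the phantom; the phantom itself is
#'   deterministic, the seed also drives [simulate_projections()] defaults.
#' @return An object of class `vessel_phantom` with elements
#'   `attenuation` ([volume_image()]), `vessel_mask` ([binary_mask()]),
#'   `centerline` (a [centerline()] sampled from the analytic curve),
#'   `diameter_profile` (mm per control point), and `seed`.
#' @examples
#' ph <- make_vessel_phantom(shape = c(96, 96), seed = 1)
#' ph
#' @export
make_vessel_phantom <- function(shape = c(192L, 192L), voxel_pitch = 0.1,
                                arch_radius = 5, tube_radius = 0.6,
                                arch_span_deg = 180, branch_length = 0,
                                body_radius = 7.5,
                                mu_background = 0.02, mu_vessel = 0.06,
                                mu_bone = 0.10, bone_radius = 1.0,
                                centerline_spacing = voxel_pitch / 2,
                                seed = 1L) {
  nd <- length(shape)
  if (!nd %in% c(2L, 3L)) stop("shape must have 2 or 3 dimensions", call. = FALSE)
  if (tube_radius < 2 * voxel_pitch)
    stop("tube radius below 2 voxels: the vessel diameter is not resolvable on this grid",
         call. = FALSE)
  if (mu_background >= mu_vessel)
    stop("vessel attenuation must exceed the background", call. = FALSE)
  if (centerline_spacing > voxel_pitch)
    stop("centerline must be sampled at no more than one voxel spacing", call. = FALSE)
  shape <- as.integer(shape)
  origin <- -shape * voxel_pitch / 2

  cl <- analytic_centerline(arch_radius, arch_span_deg, branch_length,
                            centerline_spacing, nd)
  cl$diameters <- rep(2 * tube_radius, nrow(cl$points))

  # voxel centre coordinates
  ax <- lapply(seq_len(nd), function(a) origin[a] + (seq_len(shape[a]) - 0.5) * voxel_pitch)
  if (nd == 2) {
    grid <- cbind(rep(ax[[1]], times = shape[2]),
                  rep(ax[[2]], each = shape[1]))
  } else {
    grid <- cbind(rep(ax[[1]], times = shape[2] * shape[3]),
                  rep(rep(ax[[2]], each = shape[1]), times = shape[3]),
                  rep(ax[[3]], each = shape[1] * shape[2]))
  }
  dvessel <- dist_to_polyline(grid, cl$points)
  vessel <- array(dvessel <= tube_radius, dim = shape)

  # circular/spherical body centred on the rotation axis
  r2 <- rowSums(grid^2)
  body <- array(r2 <= body_radius^2, dim = shape)

  mu <- array(0, dim = shape)
  mu[body] <- mu_background
  mu[vessel] <- mu_vessel

  if (bone_radius > 0) {
    # bone insert placed opposite the arch, inside the body
    bc <- c(-0.6 * body_radius, -0.6 * body_radius, rep(0, nd - 2))[seq_len(nd)]
    db2 <- rowSums(sweep(grid, 2, bc)^2)
    bone <- array(db2 <= bone_radius^2, dim = shape)
    mu[bone & body] <- mu_bone
  }

  structure(
    list(attenuation = volume_image(mu, voxel_pitch, origin),
         vessel_mask = binary_mask(vessel, voxel_pitch, origin),
         centerline = cl,
         diameter_profile = rep(2 * tube_radius, nrow(cl$points)),
         tube_radius = tube_radius,
         seed = as.integer(seed)),
    class = "vessel_phantom")
}

#' @export
print.vessel_phantom <- function(x, ...) {
  cat(sprintf("<vessel_phantom> grid %s @ %.3g mm\n",
              paste(dim(x$attenuation$values), collapse = " x "),
              x$attenuation$voxel_pitch))
  cat(sprintf("  vessel: %d voxels, true diameter %.3g mm, centerline %d points\n",
              sum(x$vessel_mask$values), 2 * x$tube_radius, nrow(x$centerline$points)))
  invisible(x)
}

# Analytic arch centreline: an arc of radius R spanning `span` degrees,
# traversed from angle 0, plus an optional straight tangential branch from
# the far end.  2D: arc in the x-y plane.  3D: the arch bends in the x-z
# plane (an upright arch), y = 0.
analytic_centerline <- function(R, span_deg, branch_length, spacing, nd) {
  span <- span_deg * pi / 180
  arc_len <- R * span
  n_arc <- max(2L, ceiling(arc_len / spacing) + 1L)
  phi <- seq(0, span, length.out = n_arc)
  if (nd == 2) {
    pts <- cbind(R * cos(phi), R * sin(phi))
    tans <- cbind(-sin(phi), cos(phi))
  } else {
    pts <- cbind(R * cos(phi), rep(0, n_arc), R * sin(phi))
    tans <- cbind(-sin(phi), rep(0, n_arc), cos(phi))
  }
  if (branch_length > 0) {
    tdir <- tans[n_arc, ]
    nb <- max(1L, ceiling(branch_length / spacing))
    sb <- seq_len(nb) / nb * branch_length
    bp <- sweep(outer(sb, tdir), 2, pts[n_arc, ], `+`)
    pts <- rbind(pts, bp)
    tans <- rbind(tans, matrix(tdir, nb, nd, byrow = TRUE))
  }
  centerline(pts, tangents = tans, diameters = rep(2, nrow(pts)))
}

# Minimum Euclidean distance from each query point to a densely sampled
# polyline (points are at sub-voxel spacing, so point sampling is an
# adequate stand-in for true curve distance at voxel resolution).  Chunked
# to bound memory.
dist_to_polyline <- function(q, pts) {
  n <- nrow(q)
  out <- numeric(n)
  step <- max(1L, floor(2^22 / nrow(pts)))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + step - 1L)
    block <- q[i:j, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(pts^2), `+`) -
      2 * block %*% t(pts)
    out[i:j] <- sqrt(pmax(apply(d2, 1, min), 0))
    i <- j + 1L
  }
  out
}

#' Simulate projection data from a phantom
#'
#' Forward-projects the phantom attenuation through the scan geometry
#' (Beer-Lambert line integrals) and, for a finite photon budget, draws
#' Poisson photon counts `c ~ Poisson(I0 * exp(-L))` per detector pixel and
#' returns the log-transformed measurement `m = -log(max(c, 1) / I0)`.
#' Counts are clamped at 1 so the log stays finite.  With
#' `photons = Inf` the exact noise-free line integrals are returned.  The
#' paper-style dose ladder is emulated by view subsampling at a fixed
#' per-view photon budget ([subsample_views()]); reducing `photons` at a
#' fixed view count emulates tube-current reduction instead.
#'
#' @param truth a `vessel_phantom` (or any [volume_image()]).
#' @param geom a [scan_geometry()].
#' @param photons incident photons per detector pixel (`I0 > 0`, possibly
#'   `Inf` for noise-free data).
#' @param seed integer seed for the Poisson draw; defaults to the phantom's
#'   own seed.
#' @return A [projection_data()] object.
#' @export
simulate_projections <- function(truth, geom, photons = Inf, seed = NULL) {
  vol <- if (inherits(truth, "vessel_phantom")) truth$attenuation else truth
  stopifnot(inherits(vol, "volume_image"))
  if (!is.numeric(photons) || length(photons) != 1 || is.na(photons) || photons <= 0)
    stop("photons must be a positive number (or Inf for noise-free data)", call. = FALSE)
  L <- forward_project(vol, geom)
  if (!is.finite(photons)) return(L)
  if (is.null(seed))
    seed <- if (inherits(truth, "vessel_phantom")) truth$seed else 1L
  vals <- L$values
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  counts <- array(stats::rpois(length(vals), photons * exp(-vals)), dim = dim(vals))
  m <- -log(pmax(counts, 1) / photons)
  projection_data(m, geom, photon_budget = photons,
                  neg_tol = 12 / sqrt(photons))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
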