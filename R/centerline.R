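#' Centerline of a tubular segmentation
#'
#' An ordered polyline of control points (mm coordinates) with unit tangent
#' vectors and a best-fit lumen diameter per point.
#'
#' @param points numeric matrix, one control point per row (2 or 3 columns).
#' @param tangents matrix of the same shape; rows are normalized.
#' @param diameters positive diameters in mm, one per point.
#' @param spacing optional nominal control-point spacing in mm.
#' @return An object of class `centerline`.
#' @export
centerline <- function(points, tangents, diameters, spacing = NULL) {
  points <- as.matrix(points)
  tangents <- as.matrix(tangents)
  if (nrow(points) < 2) stop("a centerline needs at least 2 points", call. = FALSE)
  if (!identical(dim(points), dim(tangents)))
    stop("points and tangents must have matching shape", call. = FALSE)
  steps <- sqrt(rowSums((points[-1, , drop = FALSE] -
                           points[-nrow(points), , drop = FALSE])^2))
  if (any(steps == 0)) stop("consecutive control points must be distinct", call. = FALSE)
  nrm <- sqrt(rowSums(tangents^2))
  if (any(nrm == 0)) stop("tangents must be nonzero", call. = FALSE)
  tangents <- tangents / nrm
  diameters <- as.numeric(diameters)
  if (length(diameters) != nrow(points) || any(!is.finite(diameters)) ||
      any(diameters <= 0))
    stop("diameters must be positive, one per control point", call. = FALSE)
  structure(list(points = points, tangents = tangents,
                 diameters = diameters, spacing = spacing),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  L <- sum(sqrt(rowSums((x$points[-1, , drop = FALSE] -
                           x$points[-nrow(x$points), , drop = FALSE])^2)))
  cat(sprintf("<centerline> %d control points, length %.3g mm, diameter %.3g +/- %.2g mm\n",
              nrow(x$points), L, mean(x$diameters), stats::sd(x$diameters)))
  invisible(x)
}

#' Euclidean distance transform of a binary mask
#'
#' Exact Euclidean distance (mm) from each foreground voxel centre to the
#' nearest background voxel centre, computed with the separable
#' lower-envelope algorithm.  Background voxels get distance 0.
#'
#' @param mask a [binary_mask()].
#' @return A [volume_image()] of distances in mm.
#' @export
distance_transform <- function(mask) {
  x <- mask_values(mask)
  g <- array(0, dim(x))
  g[x] <- 1e18
  for (a in seq_along(dim(x))) g <- edt_axis(g, a)
  pitch <- if (inherits(mask, "binary_mask")) mask$voxel_pitch else 1
  origin <- if (inherits(mask, "binary_mask")) mask$origin else NULL
  volume_image(sqrt(g) * pitch, voxel_pitch = pitch, origin = origin)
}

# 1D squared-distance lower envelope (Felzenszwalb-Huttenlocher).
edt_sq_1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * (q - v[k]))
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * (q - v[k]))
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  d <- numeric(n)
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

edt_axis <- function(g, axis) {
  d <- dim(g)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  gp <- aperm(g, perm)
  m <- matrix(gp, nrow = d[axis])
  m <- apply(m, 2, edt_sq_1d)
  gp <- array(m, dim(gp))
  aperm(gp, order(perm))
}

#' Extract a centerline from a tubular binary mask
#'
#' Replacement for interactive vendor centerline tools: the mask's Euclidean
#' distance transform defines a medialness ridge; mask voxels are connected
#' into a graph (full 26/8-neighbourhood, edge cost = step length divided by
#' the local distance-to-boundary) and the longest geodesic path through the
#' tube is found by two sweeps of Dijkstra's algorithm; the voxel chain is
#' then smoothed with a moving average and resampled at a fixed control
#' point spacing.  Tangents come from central differences, diameters from
#' [diameter_at_point()] at each control point.
#'
#' @param mask a [binary_mask()] containing one connected tubular component
#'   (if several components are present the largest is used, with a
#'   warning).
#' @param spacing control point spacing in mm (default: 2 voxel pitches).
#' @param smooth_window moving-average half-width in voxels; default is the
#'   estimated tube radius in voxels.
#' @param diameter_mode passed to [diameter_at_point()].
#' @return A [centerline()].
#' @export
extract_centerline <- function(mask, spacing = NULL, smooth_window = NULL,
                               diameter_mode = c("area", "circle")) {
  diameter_mode <- match.arg(diameter_mode)
  stopifnot(inherits(mask, "binary_mask"))
  x <- mask$values
  pitch <- mask$voxel_pitch
  origin <- mask$origin
  if (is.null(spacing)) spacing <- 2 * pitch
  nd <- length(dim(x))
  if (sum(x) < 3)
    stop("mask too small to carry a centerline", call. = FALSE)

  dt <- distance_transform(mask)$values

  vox <- which(x)                      # linear indices of foreground
  id <- integer(length(x)); id[vox] <- seq_along(vox)
  off <- neighbour_offsets(nd)
  # keep one direction per offset pair to avoid duplicate edges
  off <- off[apply(off, 1, function(o) { nz <- o[o != 0]; nz[length(nz)] > 0 }), , drop = FALSE]
  edges <- NULL; weights <- NULL
  for (r in seq_len(nrow(off))) {
    o <- off[r, ]
    sh <- shift_mask(x, o, fill = FALSE)      # neighbour at +o exists
    both <- x & sh
    from <- which(both)
    if (length(from) == 0) next
    d <- dim(x)
    stride <- cumprod(c(1, d[-nd]))
    to <- from + sum(o * stride)
    step <- sqrt(sum(o^2)) * pitch
    wij <- step * 0.5 * (1 / (dt[from] + 0.5 * pitch) + 1 / (dt[to] + 0.5 * pitch)) * pitch
    edges <- c(edges, rbind(id[from], id[to]))
    weights <- c(weights, wij)
  }
  g <- igraph::make_graph(edges, n = length(vox), directed = FALSE)
  igraph::E(g)$weight <- weights
  comp <- igraph::components(g)
  if (comp$no > 1) {
    warning("mask has ", comp$no, " connected components; using the largest")
    keepc <- which.max(comp$csize)
    sub <- which(comp$membership == keepc)
    g <- igraph::induced_subgraph(g, sub)
    vox <- vox[sub]
  }

  d1 <- igraph::distances(g, v = 1)
  e1 <- which.max(replace(d1, !is.finite(d1), -Inf))
  d2 <- igraph::distances(g, v = e1)
  e2 <- which.max(replace(d2, !is.finite(d2), -Inf))
  vp <- igraph::shortest_paths(g, from = e1, to = e2, output = "vpath")$vpath[[1]]
  chain <- vox[as.integer(vp)]
  if (length(chain) < 3)
    stop("mask does not contain a resolvable tubular path", call. = FALSE)

  ai <- arrayInd(chain, dim(x))
  pts <- sweep((ai - 0.5) * pitch, 2, origin, `+`)

  r_est <- stats::median(dt[chain])
  if (is.null(smooth_window)) smooth_window <- max(1L, round(r_est / pitch))
  pts <- moving_average_rows(pts, smooth_window)

  # drop one tube radius of arc length at each end: the geodesic endpoints
  # sit on the tube end caps, where the medial path bends toward corners
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L > 4 * r_est) {
    keep <- s >= r_est & s <= L - r_est
    if (sum(keep) >= 3) pts <- pts[keep, , drop = FALSE]
  }

  rs <- resample_polyline(pts, spacing)
  tans <- polyline_tangents(rs)

  dia <- vapply(seq_len(nrow(rs)), function(i) {
    tryCatch(diameter_at_point(mask, rs[i, ], tans[i, ], mode = diameter_mode),
             error = function(e) NA_real_)
  }, numeric(1))
  keep <- is.finite(dia) & dia > 0
  if (sum(keep) < 2)
    stop("could not measure diameters along the extracted path", call. = FALSE)
  centerline(rs[keep, , drop = FALSE], tans[keep, , drop = FALSE],
             dia[keep], spacing = spacing)
}

# Moving average over rows with half-window h, partial windows at the ends.
moving_average_rows <- function(p, h) {
  if (h < 1) return(p)
  n <- nrow(p)
  out <- p
  cs <- apply(rbind(0, p), 2, cumsum)
  for (i in seq_len(n)) {
    a <- max(1L, i - h); b <- min(n, i + h)
    out[i, ] <- (cs[b + 1L, ] - cs[a, ]) / (b - a + 1L)
  }
  out
}

resample_polyline <- function(p, spacing) {
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  keep <- c(TRUE, seg > 0)
  p <- p[keep, , drop = FALSE]; s <- s[keep]
  L <- s[length(s)]
  if (L <= 0) stop("degenerate path", call. = FALSE)
  m <- max(2L, floor(L / spacing) + 1L)
  st <- seq(0, L, length.out = m)
  out <- matrix(0, m, ncol(p))
  for (a in seq_len(ncol(p)))
    out[, a] <- stats::approx(s, p[, a], xout = st)$y
  out
}

polyline_tangents <- function(p) {
  n <- nrow(p)
  t <- p
  t[1, ] <- p[2, ] - p[1, ]
  t[n, ] <- p[n, ] - p[n - 1, ]
  if (n > 2)
    t[2:(n - 1), ] <- p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE]
  t / sqrt(rowSums(t^2))
}

# Linear (bi/trilinear) interpolation of an array at mm points.
interp_volume <- function(values, pts, pitch, origin) {
  pts <- matrix(pts, ncol = length(dim(values)))
  nd <- ncol(pts)
  d <- dim(values)
  gc_ <- sweep(pts, 2, origin) / pitch - 0.5
  base <- floor(gc_)
  frac <- gc_ - base
  out <- numeric(nrow(pts))
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  stride <- cumprod(c(1, d[-nd]))
  for (r in seq_len(nrow(corners))) {
    idx <- sweep(base, 2, corners[r, ], `+`)          # 0-based
    w <- rep(1, nrow(pts))
    ok <- rep(TRUE, nrow(pts))
    for (a in seq_len(nd)) {
      w <- w * ifelse(corners[r, a] == 1, frac[, a], 1 - frac[, a])
      ok <- ok & idx[, a] >= 0 & idx[, a] < d[a]
    }
    lin <- as.integer(idx %*% stride) + 1L
    lin[!ok] <- 1L
    out <- out + ifelse(ok, w * values[lin], 0)
  }
  out
}

#' Best-fit lumen diameter at a centerline point
#'
#' Measures the vessel diameter on the plane orthogonal to the centerline
#' tangent through a control point.  The mask is resampled on that plane on
#' a sub-voxel grid (linear interpolation, step = half the voxel pitch,
#' threshold 0.5); the connected cross-section containing the point is
#' isolated and its diameter reported either as the equivalent-area circle
#' diameter `2*sqrt(area/pi)` (`mode = "area"`, default) or as the diameter
#' of a least-squares circle fit to the cross-section boundary
#' (`mode = "circle"`).  In 2D the "plane" is the orthogonal line and the
#' diameter is the length of the contiguous in-mask run through the point.
#'
#' @param mask a [binary_mask()].
#' @param point numeric mm coordinates; must lie inside the mask.
#' @param tangent local centerline direction (any nonzero vector).
#' @param mode `"area"` or `"circle"`.
#' @param halfwidth half-extent of the sampling plane in mm (default 2.5).
#' @return Diameter in mm.
#' @export
diameter_at_point <- function(mask, point, tangent, mode = c("area", "circle"),
                              halfwidth = 2.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(mask, "binary_mask"))
  x <- mask$values
  pitch <- mask$voxel_pitch
  origin <- mask$origin
  nd <- length(dim(x))
  stopifnot(length(point) == nd, length(tangent) == nd)
  vals <- x * 1
  if (interp_volume(vals, point, pitch, origin) < 0.5)
    stop("the query point lies outside the mask", call. = FALSE)
  t <- tangent / sqrt(sum(tangent^2))
  step <- pitch / 2
  s <- seq(-halfwidth, halfwidth, by = step)
  ctr <- which.min(abs(s))
  if (nd == 2) {
    nrm <- c(-t[2], t[1])
    pts <- cbind(point[1] + s * nrm[1], point[2] + s * nrm[2])
    prof <- interp_volume(vals, pts, pitch, origin)
    run <- contiguous_run(prof >= 0.5, ctr)
    # extend by one sample each side to pick up the partial boundary samples
    ext <- run | c(run[-1], FALSE) | c(FALSE, run[-length(run)])
    return(sum(prof[ext]) * step)
  }
  aux <- c(0, 0, 0); aux[which.min(abs(t))] <- 1
  e1 <- cross3(t, aux); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(t, e1)
  g <- expand.grid(s1 = s, s2 = s)
  pts <- cbind(point[1] + g$s1 * e1[1] + g$s2 * e2[1],
               point[2] + g$s1 * e1[2] + g$s2 * e2[2],
               point[3] + g$s1 * e1[3] + g$s2 * e2[3])
  vm <- matrix(interp_volume(vals, pts, pitch, origin), length(s), length(s))
  inside <- vm >= 0.5
  seedm <- matrix(FALSE, length(s), length(s)); seedm[ctr, ctr] <- TRUE
  compo <- region_grow(inside, seedm)
  if (mode == "area") {
    # fractional (interpolated) area over the component and its one-sample
    # boundary band: smoother than counting thresholded samples
    band <- mask_values(dilate26(compo))
    area <- sum(vm[band]) * step^2
    return(2 * sqrt(area / pi))
  }
  bnd <- compo & !erode26(compo)
  idx <- which(bnd, arr.ind = TRUE)
  if (nrow(idx) < 3) {
    area <- sum(compo) * step^2
    return(2 * sqrt(area / pi))
  }
  xy <- cbind(s[idx[, 1]], s[idx[, 2]])
  2 * kasa_circle_radius(xy)
}

contiguous_run <- function(v, i0) {
  if (!v[i0]) return(logical(length(v)))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- which(starts <= i0 & ends >= i0)
  out <- logical(length(v))
  out[starts[k]:ends[k]] <- TRUE
  out
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Algebraic (Kasa) least-squares circle fit; returns the radius.
kasa_circle_radius <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  sqrt(sol[3] + sol[1]^2 + sol[2]^2)
}
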