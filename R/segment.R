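#' Intensity statistics inside a volume of interest
#'
#' Computes the mean, sample standard deviation (n - 1 denominator),
#' minimum and maximum of the voxel values inside a user-marked seed region
#' (VOI) placed inside the vessel lumen.  These statistics drive the
#' threshold interval of [threshold_segment()].
#'
#' @param vol a [volume_image()].
#' @param voi a [binary_mask()] (or logical array) of the same shape.
#' @return An object of class `voi_stats` with fields `mean`, `sd`, `min`,
#'   `max`, `n`.
#' @export
voi_statistics <- function(vol, voi) {
  v <- mask_values(voi)
  x <- vol$values
  if (!identical(dim(v), dim(x)))
    stop("VOI shape does not match the volume", call. = FALSE)
  vals <- x[v]
  if (length(vals) == 0) stop("the VOI is empty", call. = FALSE)
  structure(list(mean = mean(vals),
                 sd = if (length(vals) > 1) stats::sd(vals) else 0,
                 min = min(vals), max = max(vals), n = length(vals)),
            class = "voi_stats")
}

#' @export
print.voi_stats <- function(x, ...) {
  cat(sprintf("<voi_stats> n = %d: mean %.5g, sd %.5g, range [%.5g, %.5g]\n",
              x$n, x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' Preliminary threshold segmentation from VOI statistics
#'
#' Selects voxels with values in the closed interval
#' `[max(v_min, mean - 3*sd), min(v_max, mean + 3*sd)]`: three standard
#' deviations around the VOI mean, clamped to the range actually observed
#' inside the VOI.
#'
#' @param vol a [volume_image()].
#' @param stats a `voi_stats` object from [voi_statistics()].
#' @return A [binary_mask()] aligned with `vol`.
#' @export
threshold_segment <- function(vol, stats) {
  stopifnot(inherits(stats, "voi_stats"))
  lower <- max(stats$min, stats$mean - 3 * stats$sd)
  upper <- min(stats$max, stats$mean + 3 * stats$sd)
  stopifnot(lower <= upper)
  binary_mask(vol$values >= lower & vol$values <= upper,
              voxel_pitch = vol$voxel_pitch, origin = vol$origin)
}

# Enumerate the full neighbourhood offsets: 26-connectivity in 3D, its
# 8-connectivity analogue in 2D.
neighbour_offsets <- function(nd) {
  off <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  off[rowSums(off != 0) > 0, , drop = FALSE]
}

# Shift a logical array by an integer offset, padding with `fill`
# (the outside-volume policy: background).
shift_mask <- function(x, off, fill = FALSE) {
  d <- dim(x)
  idx <- vector("list", length(d))
  out <- array(fill, d)
  src <- vector("list", length(d))
  for (a in seq_along(d)) {
    o <- off[a]
    if (o >= 0) { idx[[a]] <- seq_len(d[a] - o) + o; src[[a]] <- seq_len(d[a] - o) }
    else        { idx[[a]] <- seq_len(d[a] + o);     src[[a]] <- seq_len(d[a] + o) - o }
    if (length(idx[[a]]) == 0) return(out)
  }
  out <- do.call(`[<-`, c(list(out), src, list(value = do.call(`[`, c(list(x), idx, list(drop = FALSE))))))
  out
}

#' Morphological erosion over the full neighbourhood
#'
#' A voxel stays foreground only if it and all of its 26 neighbours (8 in
#' 2D) are foreground; positions outside the volume count as background, so
#' the border shell of an all-true volume is removed.  This replaces each
#' voxel with the minimum over its neighbourhood.
#'
#' @param mask a [binary_mask()] or logical array.
#' @return The same type as the input.
#' @seealso [dilate26()], [fill_holes()]
#' @export
erode26 <- function(mask) {
  morph_apply(mask, all_of = TRUE)
}

#' Morphological dilation over the full neighbourhood
#'
#' The dual of [erode26()]: a voxel becomes foreground if it or any of its
#' 26 neighbours (8 in 2D) is foreground (maximum over the neighbourhood).
#' Applied after region growing to regain the volume removed by the initial
#' erosion.
#'
#' @inheritParams erode26
#' @return The same type as the input.
#' @export
dilate26 <- function(mask) {
  morph_apply(mask, all_of = FALSE)
}

morph_apply <- function(mask, all_of) {
  x <- mask_values(mask)
  off <- neighbour_offsets(length(dim(x)))
  out <- x
  for (r in seq_len(nrow(off))) {
    s <- shift_mask(x, off[r, ], fill = FALSE)
    out <- if (all_of) out & s else out | s
  }
  rewrap_mask(out, mask)
}

rewrap_mask <- function(values, like) {
  if (inherits(like, "binary_mask"))
    binary_mask(values, voxel_pitch = like$voxel_pitch, origin = like$origin)
  else values
}

#' Seeded region growing within a candidate mask
#'
#' Returns the part of `candidate` reachable from the seed VOI through
#' 26-connected (8-connected in 2D) foreground paths, i.e. the connected
#' component(s) of the candidate mask that intersect the seed.  The result
#' is always a subset of the candidate.
#'
#' @param candidate a [binary_mask()] or logical array (e.g. the threshold
#'   mask after erosion).
#' @param seed_voi a [binary_mask()] or logical array of seed voxels.
#' @return The same type as `candidate`.
#' @export
region_grow <- function(candidate, seed_voi) {
  cand <- mask_values(candidate)
  seed <- mask_values(seed_voi)
  if (!identical(dim(cand), dim(seed)))
    stop("seed and candidate masks must have the same shape", call. = FALSE)
  grow <- cand & seed
  if (!any(grow))
    stop("the seed VOI does not intersect the candidate mask; nothing to grow",
         call. = FALSE)
  off <- neighbour_offsets(length(dim(cand)))
  repeat {
    nxt <- grow
    for (r in seq_len(nrow(off)))
      nxt <- nxt | shift_mask(grow, off[r, ], fill = FALSE)
    nxt <- nxt & cand
    if (identical(nxt, grow)) break
    grow <- nxt
  }
  rewrap_mask(grow, candidate)
}

#' Fill holes in a binary mask
#'
#' Two modes are provided.  `"literal"` performs a single pass in which each
#' voxel is OR-ed with its 26 neighbours (8 in 2D) — this fills isolated
#' single-voxel holes but, being one dilation pass, also adds a one-voxel
#' shell at the object boundary and cannot close wider cavities.
#' `"topological"` fills every background region not connected to the volume
#' border (flood fill from the border, full-neighbourhood connectivity),
#' which closes enclosed cavities of any size without touching the
#' boundary.
#'
#' @inheritParams erode26
#' @param mode `"literal"` or `"topological"`.
#' @return The same type as the input.
#' @export
fill_holes <- function(mask, mode = c("literal", "topological")) {
  mode <- match.arg(mode)
  x <- mask_values(mask)
  if (mode == "literal") return(dilate26(mask))
  bg <- !x
  border <- array(FALSE, dim(x))
  d <- dim(x)
  for (a in seq_along(d)) {
    idx <- rep(list(quote(expr = )), length(d))
    for (edge in c(1L, d[a])) {
      idx[[a]] <- edge
      border <- do.call(`[<-`, c(list(border), idx, list(value = TRUE)))
      idx[[a]] <- quote(expr = )
    }
  }
  seed <- bg & border
  if (!any(seed)) return(rewrap_mask(array(TRUE, d), mask))
  outside <- region_grow(bg, seed)
  outside <- mask_values(outside)
  rewrap_mask(x | (!x & !outside), mask)
}

#' Semi-automatic vessel segmentation chain
#'
#' The full segmentation pipeline applied to a reconstructed volume with a
#' user-supplied seed VOI inside the vessel: VOI statistics, +/- 3 sigma
#' threshold ([threshold_segment()]), one-voxel erosion ([erode26()]) to
#' detach noise voxels, seeded region growing from the VOI
#' ([region_grow()]), one-voxel dilation ([dilate26()]) to regain the eroded
#' shell, and hole filling ([fill_holes()]).  The chain is fully
#' deterministic.  All intermediate masks are attached for inspection.
#'
#' @param vol a [volume_image()] (typically a reconstruction).
#' @param seed_voi a [binary_mask()] or logical array inside the vessel.
#' @param fill_mode hole-filling mode passed to [fill_holes()]; the default
#'   `"topological"` closes enclosed cavities without inflating the
#'   boundary (see the package vignette for why the literal single-pass OR
#'   is not the default here).
#' @return A [binary_mask()] with attribute `stages`, a named list of the
#'   intermediate masks (`threshold`, `eroded`, `grown`, `dilated`,
#'   `filled`).
#' @export
segment_vessels <- function(vol, seed_voi, fill_mode = c("topological", "literal")) {
  fill_mode <- match.arg(fill_mode)
  st <- voi_statistics(vol, seed_voi)
  m_thr <- threshold_segment(vol, st)
  m_ero <- erode26(m_thr)
  m_grow <- region_grow(m_ero, seed_voi)
  m_dil <- dilate26(m_grow)
  m_fill <- fill_holes(m_dil, mode = fill_mode)
  attr(m_fill, "stages") <- list(threshold = m_thr, eroded = m_ero,
                                 grown = m_grow, dilated = m_dil,
                                 filled = m_fill)
  attr(m_fill, "voi_stats") <- st
  m_fill
}
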