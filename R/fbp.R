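#' Filtered back-projection (fan-beam FBP / cone-beam FDK)
#'
#' Analytic reconstruction baseline.  In fan-beam mode this is the standard
#' flat-detector full-scan algorithm: cosine weighting of each projection,
#' ramp filtering of each view (band-limited ramp kernel, optionally
#' apodized with a Hann window), and distance-weighted back-projection with
#' the `1/U^2` fan weight, where detector coordinates are rescaled to the
#' virtual detector through the isocentre.  In cone-beam mode it is the
#' Feldkamp-Davis-Kress (FDK) extension: cone-angle cosine weighting,
#' row-wise ramp filtering, and `1/U^2`-weighted 3D back-projection.  The
#' operator is linear in the data; redundant 360-degree coverage is handled
#' by the 1/2 short-object factor.
#'
#' @param proj a [projection_data()].
#' @param filter ramp apodization window: `"hann"` (default; the exact
#'   filter of the reference commercial implementation is undocumented, so a
#'   smooth window is the conventional choice) or `"ram-lak"` (pure ramp).
#' @param vol_template optional [volume_image()] fixing the output grid.
#' @return A [volume_image()] of reconstructed attenuation values (1/mm).
#' @seealso [isra()], [isra_tv()]
#' @export
fbp <- function(proj, filter = c("hann", "ram-lak"), vol_template = NULL) {
  stopifnot(inherits(proj, "projection_data"))
  filter <- match.arg(filter)
  geom <- proj$geometry
  nv <- length(geom$angles)
  if (nv < 2)
    stop("filtered back-projection needs at least 2 views", call. = FALSE)
  if (is.null(vol_template)) vol_template <- default_grid(geom)
  mag <- magnification(geom)
  pdv <- geom$det_pitch / mag          # virtual detector pixel pitch (mm)
  nd <- geom$det_count
  u <- (seq_len(nd) - 1 - (nd - 1) / 2) * pdv
  dbeta <- 2 * pi / nv
  dm <- dim(vol_template$values)
  if (geom$mode == "fan2d") {
    w <- geom$sad / sqrt(geom$sad^2 + u^2)
    g <- sweep(proj$values, 2, w, `*`)
    q <- ramp_filter_rows(g, pdv, filter)
    out <- .cpp_back_fbp2d(q, dm[1], dm[2], vol_template$voxel_pitch,
                           vol_template$origin[1], vol_template$origin[2],
                           geom$angles, geom$sad, pdv)
    out <- out * dbeta / 2
  } else {
    nr <- geom$det_rows
    wrow <- (seq_len(nr) - 1 - (nr - 1) / 2) * pdv
    # cone cosine weight over (row, det)
    wt <- geom$sad / sqrt(geom$sad^2 + outer(wrow^2, u^2, `+`))
    g <- proj$values * rep(wt, each = nv)
    # filter along the detector axis for every (view, row)
    flat <- matrix(aperm(g, c(3, 1, 2)), nrow = nd)   # det x (views*rows)
    qf <- ramp_filter_rows(t(flat), pdv, filter)       # rows are signals
    q <- aperm(array(t(qf), dim = c(nd, nv, nr)), c(2, 3, 1))
    out <- .cpp_back_fdk3d(q, dim(q), dm, vol_template$voxel_pitch,
                           vol_template$origin[1], vol_template$origin[2],
                           vol_template$origin[3],
                           geom$angles, geom$sad, pdv)
    out <- out * dbeta / 2
  }
  volume_image(out, voxel_pitch = vol_template$voxel_pitch,
               origin = vol_template$origin)
}

# Ramp-filter each row of `g` (signals along columns index) with sample
# spacing tau, via FFT convolution with the band-limited ramp kernel
# (Ram-Lak), optionally apodized by a Hann window in frequency space.
ramp_filter_rows <- function(g, tau, filter = "hann") {
  n <- ncol(g)
  npad <- 2^ceiling(log2(2 * n))
  h <- numeric(npad)
  h[1] <- 1 / (4 * tau^2)
  k <- seq_len(npad - 1)
  odd <- k %% 2 == 1
  # circular (wrapped) kernel: index k and npad - k carry |k|
  kk <- pmin(k, npad - k)
  h[1 + k[odd]] <- -1 / (pi^2 * kk[odd]^2 * tau^2)
  H <- Re(stats::fft(h))
  if (filter == "hann") {
    f <- pmin(0:(npad - 1), npad - (0:(npad - 1))) / (npad / 2)
    H <- H * 0.5 * (1 + cos(pi * f))
  }
  gp <- cbind(g, matrix(0, nrow(g), npad - n))
  G <- t(stats::mvfft(t(gp)))
  q <- t(Re(stats::mvfft(t(G * rep(H, each = nrow(g))), inverse = TRUE))) / npad
  q[, seq_len(n), drop = FALSE] * tau
}
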