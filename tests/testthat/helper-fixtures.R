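# Shared fixtures: all built in code at test time.

# Centred uniform disc on an n x n grid; returns the volume and analytic info.
disc_volume <- function(n = 128, pitch = 0.1, radius = 4, mu = 0.05) {
  cx <- ((seq_len(n)) - 0.5) * pitch - n * pitch / 2
  d2 <- outer(cx^2, cx^2, `+`)
  v <- matrix(0, n, n)
  v[d2 <= radius^2] <- mu
  list(vol = volume_image(v, pitch), d2 = d2, radius = radius, mu = mu)
}

small_geom <- function(n_views = 8, det_count = 24, det_pitch = 0.35) {
  scan_geometry(n_views = n_views, det_pitch = det_pitch, det_count = det_count)
}

# Compact phantom fitting a 64^2 grid (half-scale arch).
small_phantom <- function(seed = 7) {
  make_vessel_phantom(shape = c(64, 64), voxel_pitch = 0.1,
                      arch_radius = 1.8, tube_radius = 0.45,
                      body_radius = 2.6, bone_radius = 0.4, seed = seed)
}

# Independent nonnegative least-squares oracle: projected gradient descent.
nnls_oracle <- function(A, b, iters = 30000) {
  x <- rep(0, ncol(A))
  L <- max(eigen(crossprod(A), only.values = TRUE)$values)
  for (i in seq_len(iters))
    x <- pmax(0, x - as.numeric(crossprod(A, A %*% x - b)) / L)
  x
}

# Central-difference numerical gradient of a scalar functional.
numeric_gradient <- function(f, x, h = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}
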