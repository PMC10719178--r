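# Shared builders for small test instances.

tiny_grid <- function(shape = c(16L, 16L, 8L), vox = 4.8) {
  voxel_grid(shape, rep(vox, 3))
}

tiny_geom <- function(grid, n_views = 8L) {
  projection_geometry(n_views = n_views, nu = grid$shape[1],
                      nv = grid$shape[3],
                      pitch_mm = grid$voxel_size_mm[c(1, 3)],
                      radius_mm = 1.4 * grid$shape[1] * grid$voxel_size_mm[1] / 2)
}

# smooth blob strictly inside the inscribed circle (zero outside), so the
# rotating projector conserves its mass exactly
tiny_blob <- function(grid, frac = 0.55) {
  d <- grid$shape
  ax <- lapply(1:3, function(a) seq_len(d[a]) - (d[a] + 1) / 2)
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), 0 * ax[[3]], `+`)
  rmax <- (frac * min(d[1], d[2]) / 2)^2
  b <- exp(-3 * r2 / rmax)
  b[r2 > rmax] <- 0
  voxel_volume(b, grid, "other")
}

random_volume <- function(grid, seed = 1) {
  with_seed(seed, voxel_volume(array(runif(prod(grid$shape)), grid$shape),
                               grid, "other"))
}

# two-lesion smooth phantom for reconstruction consistency checks
smooth_phantom <- function(grid) {
  d <- grid$shape
  ax <- lapply(1:3, function(a) seq_len(d[a]) - (d[a] + 1) / 2)
  g3 <- function(c0, s) {
    dx2 <- outer(outer((ax[[1]] - c0[1])^2, (ax[[2]] - c0[2])^2, `+`),
                 (ax[[3]] - c0[3])^2, `+`)
    exp(-dx2 / (2 * s^2))
  }
  v <- g3(c(-1.5, 0.5, 0), 2.2) + 2 * g3(c(2, -1, 0.5), 1.4)
  rin <- (0.45 * min(d[1], d[2]))^2
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), 0 * ax[[3]], `+`)
  v[r2 > rin] <- 0
  voxel_volume(v, grid, "activity_MBq")
}
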