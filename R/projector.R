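#' SPECT acquisition geometry
#'
#' Parallel-hole geometry: `n_views` equally spaced view angles over 360
#' degrees (counter-clockwise from 0), a detector of `nu x nv` bins at
#' `pitch_mm`, a circular orbit of radius `radius_mm`, and the bremsstrahlung
#' acquisition energy window (105-195 keV by default).
#'
#' The projector binds the detector axes to the volume axes: `u` is the
#' in-plane transverse axis (must match the volume x/y pitch) and `v` is the
#' axial axis (must match the volume z pitch).
#'
#' @param n_views number of views (>= 1).
#' @param nu,nv detector bins.
#' @param pitch_mm bin pitch, length 2 (u, v).
#' @param radius_mm radius of rotation (face of collimator to axis).
#' @param window_keV acquisition energy window, c(lower, upper).
#' @return object of class `projection_geometry`.
#' @export
projection_geometry <- function(n_views = 128L, nu = 128L, nv = 80L,
                                pitch_mm = c(4.8, 4.8), radius_mm = 250,
                                window_keV = c(105, 195)) {
  stopifnot(n_views >= 1, nu >= 1, nv >= 1, all(pitch_mm > 0),
            window_keV[1] < window_keV[2])
  structure(list(n_views = as.integer(n_views),
                 angles_deg = (seq_len(n_views) - 1) * 360 / n_views,
                 nu = as.integer(nu), nv = as.integer(nv),
                 pitch_mm = as.numeric(pitch_mm),
                 radius_mm = radius_mm,
                 window_keV = as.numeric(window_keV)),
            class = "projection_geometry")
}

#' Collimator-detector response model
#'
#' Depth-dependent Gaussian blur whose FWHM grows affinely with the
#' source-to-collimator distance: `fwhm(d) = c0 + c1 * d` (mm). The defaults
#' (c0 = 2 mm, c1 = 0.05) give a broad, high-energy-collimator-like
#' response. `enabled = FALSE` switches the blur off entirely.
#'
#' @param c0_mm intrinsic FWHM at the collimator face (>= 0).
#' @param c1 FWHM growth per mm of distance (>= 0).
#' @param enabled logical.
#' @export
cdr_model <- function(c0_mm = 2, c1 = 0.05, enabled = TRUE) {
  stopifnot(c0_mm >= 0, c1 >= 0)
  structure(list(c0_mm = c0_mm, c1 = c1, enabled = enabled),
            class = "cdr_model")
}

.proj_kinds <- c("mean_primary", "mean_scatter", "noisy_counts",
                 "attenuation_line_integral", "mean_total", "estimate")

#' Per-view projection data
#'
#' A `nu x nv x n_views` array of bin values plus its geometry and a kind
#' tag. Counts and means must be non-negative and finite; `noisy_counts`
#' must be integer-valued.
#'
#' @param values numeric array `nu x nv x n_views`.
#' @param geometry a `projection_geometry`.
#' @param kind one of "mean_primary", "mean_scatter", "noisy_counts",
#'   "attenuation_line_integral", "mean_total", "estimate".
#' @export
projection_set <- function(values, geometry, kind) {
  kind <- match.arg(kind, .proj_kinds)
  values <- as.array(values)
  stopifnot(all(dim(values) == c(geometry$nu, geometry$nv, geometry$n_views)))
  if (!all(is.finite(values)) || any(values < 0))
    stop("projection_set: values must be finite and non-negative")
  if (kind == "noisy_counts" && any(values != round(values)))
    stop("projection_set: noisy_counts must be integers")
  structure(list(values = values, geometry = geometry, kind = kind),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection_set [%s] %d views %dx%d, total %.6g>\n",
              x$kind, x$geometry$n_views, x$geometry$nu, x$geometry$nv,
              sum(x$values)))
  invisible(x)
}

# sparse bilinear in-plane rotation operator for one view angle, built by
# mass-preserving splatting: each input voxel's content is distributed with
# bilinear weights at its rotated position in the detector frame
# (u, b) = (r . t_hat, r . n_hat) with t = (cos a, sin a), n = (-sin a, cos a).
# Weights sum to 1 per input voxel whenever the rotated position stays inside
# the plane, so bin sums equal the activity sum exactly for objects inside
# the inscribed field of view. Summing the rotated volume over its second
# axis projects onto the transverse detector coordinate u.
rotation_operator <- function(nx, ny, angle_deg) {
  a <- angle_deg * pi / 180
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  x <- rep(seq_len(nx) - cx, times = ny)
  y <- rep(seq_len(ny) - cy, each = nx)
  us <- cos(a) * x + sin(a) * y + cx
  bs <- -sin(a) * x + cos(a) * y + cy
  u0 <- floor(us); b0 <- floor(bs)
  fu <- us - u0; fb <- bs - b0
  n_pix <- nx * ny
  rows <- integer(0); cols <- integer(0); w <- numeric(0)
  for (du in 0:1) for (db in 0:1) {
    ui <- u0 + du; bi <- b0 + db
    wt <- (if (du == 0) 1 - fu else fu) * (if (db == 0) 1 - fb else fb)
    ok <- ui >= 1 & ui <= nx & bi >= 1 & bi <= ny & wt > 0
    rows <- c(rows, (bi[ok] - 1L) * nx + ui[ok])
    cols <- c(cols, which(ok))
    w <- c(w, wt[ok])
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = w, dims = c(n_pix, n_pix))
}

# dense 1-D Gaussian blur matrix (kernel normalised to sum 1, zero-padded
# edges) for a line of n samples at the given pitch
blur_matrix <- function(n, pitch_mm, fwhm_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  if (sigma < 1e-3 * pitch_mm) return(Matrix::Diagonal(n))
  r <- min(n - 1L, max(1L, ceiling(3 * sigma / pitch_mm)))
  k <- stats::dnorm(seq(-r, r) * pitch_mm, sd = sigma)
  k <- k / sum(k)
  B <- matrix(0, n, n)
  for (j in seq(-r, r)) {
    idx <- seq_len(n)
    tgt <- idx + j
    ok <- tgt >= 1 & tgt <= n
    B[cbind(tgt[ok], idx[ok])] <- B[cbind(tgt[ok], idx[ok])] + k[j + r + 1]
  }
  B
}

#' Precomputed SPECT system model
#'
#' Assembles the linear system operator A for a given attenuation map,
#' geometry, collimator-detector response and efficiency: per view the
#' volume is rotated into the detector frame (sparse bilinear operator),
#' attenuated by the cumulative exp(-integral mu dl) towards the detector,
#' blurred per depth plane with the depth-dependent CDR Gaussian, summed
#' along the ray axis and scaled by the efficiency. Rotation operators,
#' attenuation factors and blur matrices are precomputed here so repeated
#' projections (OS-EM) are cheap; `project()`/`backproject()` are exact
#' adjoints by construction.
#'
#' @param mu `voxel_volume` with quantity "attenuation_per_cm" (or NULL for
#'   no attenuation).
#' @param geom a `projection_geometry`.
#' @param cdr a [cdr_model()].
#' @param efficiency scalar detector efficiency (> 0).
#' @param grid required if `mu` is NULL: the volume grid.
#' @return object of class `spect_system`.
#' @export
spect_system <- function(mu, geom, cdr = cdr_model(), efficiency = 1,
                         grid = NULL) {
  if (is.null(mu)) {
    stopifnot(!is.null(grid))
    mu <- voxel_volume(array(0, grid$shape), grid, "attenuation_per_cm")
  }
  stopifnot(inherits(mu, "voxel_volume"), efficiency > 0)
  grid <- mu$grid
  d <- grid$shape
  vs <- grid$voxel_size_mm
  if (abs(vs[1] - vs[2]) > 1e-9)
    stop("spect_system: in-plane voxel sizes must be isotropic for the rotating projector")
  if (abs(vs[1] - geom$pitch_mm[1]) > 1e-9 || abs(vs[3] - geom$pitch_mm[2]) > 1e-9)
    stop("spect_system: voxel size does not match detector bin pitch; resample the volume first")
  if (d[1] != geom$nu || d[3] != geom$nv)
    stop("spect_system: grid shape (nx, nz) must equal detector bins (nu, nv)")
  rot <- vector("list", geom$n_views)
  rot_t <- vector("list", geom$n_views)
  att <- vector("list", geom$n_views)
  dy_cm <- vs[2] / 10
  for (v in seq_len(geom$n_views)) {
    W <- rotation_operator(d[1], d[2], geom$angles_deg[v])
    rot[[v]] <- W
    rot_t[[v]] <- Matrix::t(W)
    mu_rot <- as.matrix(W %*% matrix(mu$values, d[1] * d[2], d[3]))
    dim(mu_rot) <- d
    # path length towards the detector at +y of the rotated frame
    s <- apply(mu_rot, c(1, 3), function(col) rev(cumsum(rev(col))))
    s <- aperm(s, c(2, 1, 3)) # back to (x, y, z)
    att[[v]] <- exp(-dy_cm * (s - 0.5 * mu_rot))
  }
  blur_u <- vector("list", d[2]); blur_v <- vector("list", d[2])
  cy <- (d[2] + 1) / 2
  for (j in seq_len(d[2])) {
    dist <- max(0, geom$radius_mm - (j - cy) * vs[2])
    fw <- if (cdr$enabled) cdr$c0_mm + cdr$c1 * dist else 0
    blur_u[[j]] <- blur_matrix(d[1], vs[1], fw)
    blur_v[[j]] <- blur_matrix(d[3], vs[3], fw)
  }
  structure(list(grid = grid, geom = geom, cdr = cdr,
                 efficiency = efficiency, mu = mu,
                 rot = rot, rot_t = rot_t, att = att,
                 blur_u = blur_u, blur_v = blur_v),
            class = "spect_system")
}

#' Forward-project an activity volume
#'
#' Applies the system operator A (rotation, attenuation, depth-dependent CDR
#' blur, ray sum, efficiency). Linear in the activity.
#'
#' @param x `voxel_volume` of activity on the system grid.
#' @param system a [spect_system()].
#' @param views optional integer subset of views (default all).
#' @return `projection_set` of kind "mean_primary".
#' @export
project <- function(x, system, views = NULL) {
  stopifnot(inherits(system, "spect_system"))
  if (!same_grid(x$grid, system$grid))
    stop("project: volume grid does not match the system grid")
  d <- system$grid$shape
  if (is.null(views)) views <- seq_len(system$geom$n_views)
  out <- array(0, c(d[1], d[3], length(views)))
  xm <- matrix(x$values, d[1] * d[2], d[3])
  for (vi in seq_along(views)) {
    v <- views[vi]
    arr <- as.matrix(system$rot[[v]] %*% xm)
    dim(arr) <- d
    arr <- arr * system$att[[v]]
    acc <- matrix(0, d[1], d[3])
    for (j in seq_len(d[2])) {
      plane <- arr[, j, ]
      acc <- acc + as.matrix(system$blur_u[[j]] %*% plane %*%
                               Matrix::t(system$blur_v[[j]]))
    }
    out[, , vi] <- acc * system$efficiency
  }
  geom <- system$geom
  if (length(views) != geom$n_views) {
    geom$n_views <- length(views)
    geom$angles_deg <- system$geom$angles_deg[views]
  }
  projection_set(pmax(out, 0), geom, "mean_primary")
}

#' Back-project (adjoint of the forward projector)
#'
#' Exact matrix adjoint of [project()]: `<A x, p> == <x, A^T p>` for all
#' x, p, which is the property OS-EM relies on.
#'
#' @param p `projection_set` (or bare array of matching shape).
#' @param system a [spect_system()].
#' @param views integer view subset matching `p`'s third dimension
#'   (default all).
#' @return `voxel_volume` on the system grid.
#' @export
backproject <- function(p, system, views = NULL) {
  vals <- if (inherits(p, "projection_set")) p$values else as.array(p)
  d <- system$grid$shape
  if (is.null(views)) views <- seq_len(system$geom$n_views)
  stopifnot(all(dim(vals) == c(d[1], d[3], length(views))))
  acc <- matrix(0, d[1] * d[2], d[3])
  arr <- array(0, d)
  for (vi in seq_along(views)) {
    v <- views[vi]
    proj <- vals[, , vi] * system$efficiency
    for (j in seq_len(d[2])) {
      arr[, j, ] <- as.matrix(Matrix::t(system$blur_u[[j]]) %*% proj %*%
                                system$blur_v[[j]])
    }
    arr <- arr * system$att[[v]]
    acc <- acc + as.matrix(system$rot_t[[v]] %*% matrix(arr, d[1] * d[2], d[3]))
  }
  voxel_volume(array(acc, d), system$grid, "other")
}

#' Line integrals of the attenuation map (projected attenuation map)
#'
#' Straight-line integrals of mu per view: no blur, no efficiency, units
#' dimensionless. This is the second input channel of the scatter network.
#'
#' @param mu `voxel_volume` of attenuation (1/cm).
#' @param geom a `projection_geometry`.
#' @return `projection_set` of kind "attenuation_line_integral".
#' @export
project_attenuation <- function(mu, geom) {
  stopifnot(inherits(mu, "voxel_volume"))
  if (any(mu$values < 0)) stop("project_attenuation: mu must be non-negative")
  d <- mu$grid$shape
  vs <- mu$grid$voxel_size_mm
  if (d[1] != geom$nu || d[3] != geom$nv)
    stop("project_attenuation: grid does not match detector bins")
  dy_cm <- vs[2] / 10
  out <- array(0, c(geom$nu, geom$nv, geom$n_views))
  mm <- matrix(mu$values, d[1] * d[2], d[3])
  for (v in seq_len(geom$n_views)) {
    W <- rotation_operator(d[1], d[2], geom$angles_deg[v])
    arr <- as.matrix(W %*% mm)
    dim(arr) <- d
    out[, , v] <- apply(arr, c(1, 3), sum) * dy_cm
  }
  projection_set(pmax(out, 0), geom, "attenuation_line_integral")
}

#' Scale mean projections to a count level and add Poisson noise
#'
#' Scales the mean projections so their total equals `target_total_counts`
#' (clinic level is ~1e7 counts over all views) and draws one Poisson count
#' per bin. The scale factor is returned so downstream consumers (scatter
#' means fed to OS-EM) can be expressed in the same count units.
#'
#' @param p `projection_set` of mean values.
#' @param target_total_counts expected total counts over all views (>= 0).
#' @param seed integer seed.
#' @return list `counts` (`projection_set` of kind "noisy_counts") and
#'   `scale` (the applied multiplier).
#' @export
add_poisson_noise <- function(p, target_total_counts, seed) {
  stopifnot(inherits(p, "projection_set"), target_total_counts >= 0)
  tot <- sum(p$values)
  if (target_total_counts == 0) {
    return(list(counts = projection_set(array(0, dim(p$values)), p$geometry,
                                        "noisy_counts"), scale = 0))
  }
  if (tot <= 0)
    stop("add_poisson_noise: mean projections sum to zero but a positive count target was requested")
  scale <- target_total_counts / tot
  counts <- with_seed(seed, stats::rpois(length(p$values), scale * p$values))
  list(counts = projection_set(array(as.numeric(counts), dim(p$values)),
                               p$geometry, "noisy_counts"),
       scale = scale)
}
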