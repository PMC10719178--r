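#' Virtual-patient phantom configuration
#'
#' Parameters of the synthetic virtual-patient generator: an ellipsoid-union
#' liver carrying ellipsoidal lesions with configurable volumes and
#' lesion-to-background uptake ratios, a multiplicative log-normal activity
#' texture inside the liver, and lung/bone/soft-tissue density compartments.
#'
#' @param seed integer seed controlling every random choice.
#' @param grid a `voxel_grid`; default is the desk-scale preset
#'   64x64x40 at 5 mm.
#' @param liver_volume_mL target liver volume.
#' @param lesion_volumes_mL numeric vector of lesion volumes (mL), possibly empty.
#' @param lesion_uptake_ratios lesion-to-background activity concentration
#'   ratios, recycled to the number of lesions.
#' @param total_activity_GBq administered activity in the liver.
#' @param texture_sigma log-domain standard deviation of the intra-liver
#'   activity texture (0 = uniform compartments).
#' @param texture_corr_mm correlation length of the texture field.
#' @param lung_density,soft_tissue_density,bone_density compartment densities
#'   in g/cm^3.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(seed = 1L,
                           grid = desk_grid(),
                           liver_volume_mL = 1500,
                           lesion_volumes_mL = c(30, 15),
                           lesion_uptake_ratios = 4,
                           total_activity_GBq = 2.0,
                           texture_sigma = 0.3,
                           texture_corr_mm = 20,
                           lung_density = 0.30,
                           soft_tissue_density = 1.00,
                           bone_density = 1.40) {
  stopifnot(all(lesion_volumes_mL > 0), all(lesion_uptake_ratios > 0),
            texture_sigma >= 0, liver_volume_mL > 0, total_activity_GBq >= 0)
  lesion_uptake_ratios <- rep_len(lesion_uptake_ratios,
                                  length(lesion_volumes_mL))
  structure(list(seed = as.integer(seed), grid = grid,
                 liver_volume_mL = liver_volume_mL,
                 lesion_volumes_mL = lesion_volumes_mL,
                 lesion_uptake_ratios = lesion_uptake_ratios,
                 total_activity_GBq = total_activity_GBq,
                 texture_sigma = texture_sigma,
                 texture_corr_mm = texture_corr_mm,
                 lung_density = lung_density,
                 soft_tissue_density = soft_tissue_density,
                 bone_density = bone_density),
            class = "phantom_config")
}

#' Desk-scale default grid (64x64x40 at 5 mm)
#'
#' The package's default working resolution: large enough for a liver with
#' lesions from a few mL up to ~900 mL, small enough that Monte Carlo,
#' reconstruction and network training run in minutes on one CPU. The
#' full-scale clinical grid is available as [full_grid()].
#' @param shape,voxel_size_mm overrides.
#' @export
desk_grid <- function(shape = c(64L, 64L, 40L), voxel_size_mm = c(5, 5, 5)) {
  voxel_grid(shape, voxel_size_mm)
}

#' Full-scale clinical CT grid (512x512x194 at 0.98x0.98x2 mm)
#' @export
full_grid <- function() voxel_grid(c(512L, 512L, 194L), c(0.98, 0.98, 2))

# logical mask of an ellipsoid given centre and semi-axes (mm, world coords)
ellipsoid_mask <- function(grid, centre_mm, semi_mm) {
  ax <- grid_axes_mm(grid)
  dx2 <- ((ax[[1]] - centre_mm[1]) / semi_mm[1])^2
  dy2 <- ((ax[[2]] - centre_mm[2]) / semi_mm[2])^2
  dz2 <- ((ax[[3]] - centre_mm[3]) / semi_mm[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# scale ellipsoid semi-axes so the voxelised volume matches the request to
# within one voxel volume (binary search on a global scale factor; for small
# shapes the attainable voxel counts are coarse, so deterministic sub-voxel
# centre jitters are tried until the tolerance is met)
ellipsoid_mask_with_volume <- function(grid, centre_mm, semi_ratio, target_mL) {
  vv <- voxel_volume_mL(grid)
  target_n <- target_mL / vv
  # analytic radius for a sphere of equal volume, then shape by ratios
  r0 <- (3 * target_mL * 1000 / (4 * pi * prod(semi_ratio)))^(1 / 3)
  jit <- rbind(c(0, 0, 0),
               as.matrix(expand.grid(x = c(-0.25, 0.1, 0.33),
                                     y = c(-0.2, 0.15, 0.4),
                                     z = c(-0.3, 0.05, 0.27))))
  for (jr in seq_len(nrow(jit))) {
    ctr <- centre_mm + jit[jr, ] * grid$voxel_size_mm
    count_at <- function(s) sum(ellipsoid_mask(grid, ctr, s * r0 * semi_ratio))
    lo <- 0.4; hi <- 2.5
    best_s <- NA; best_err <- Inf
    for (i in 1:50) {
      mid <- (lo + hi) / 2
      n <- count_at(mid)
      err <- abs(n - target_n)
      if (err < best_err) { best_err <- err; best_s <- mid }
      if (err <= 1) break
      if (n < target_n) lo <- mid else hi <- mid
      if (hi - lo < 1e-9) break
    }
    if (best_err <= 1) {
      m <- ellipsoid_mask(grid, ctr, best_s * r0 * semi_ratio)
      if (abs(sum(m) * vv - target_mL) <= vv + 1e-9) return(m)
    }
  }
  stop(sprintf("could not voxelise a %.1f mL ellipsoid to within one voxel volume",
               target_mL))
}

# mean-one multiplicative log-normal random field restricted to a mask
lognormal_texture <- function(grid, mask, sigma, corr_mm) {
  if (sigma <= 0) return(array(1, grid$shape))
  d <- grid$shape
  noise <- array(stats::rnorm(prod(d)), d)
  sig_vox <- corr_mm / grid$voxel_size_mm / 2.355
  sm <- gaussian_smooth3(noise, sig_vox)
  s <- stats::sd(sm[mask])
  if (s > 0) sm <- sm / s * sigma
  tex <- exp(sm - sigma^2 / 2)
  mu <- mean(tex[mask])
  tex / mu
}

# separable FFT-free Gaussian smoothing (small 1-D kernels along each axis)
gaussian_smooth3 <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3)
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s < 1e-6) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s); k <- k / sum(k)
    arr <- conv_axis(arr, k, a)
  }
  arr
}

# 1-D convolution of a 3-D array along axis a, replicate-padded edges
conv_axis <- function(arr, k, a) {
  d <- dim(arr); n <- d[a]; r <- (length(k) - 1L) / 2L
  perm <- c(a, setdiff(1:3, a))
  x <- aperm(arr, perm)
  dim(x) <- c(n, prod(d[-a]))
  idx <- function(i) pmin(pmax(i, 1L), n)
  out <- matrix(0, n, ncol(x))
  for (j in seq_along(k)) out <- out + k[j] * x[idx(seq_len(n) + j - 1L - r), , drop = FALSE]
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

#' Generate a synthetic virtual-patient phantom
#'
#' Builds an activity map, a density map and a VOI set emulating a
#' radioembolization patient: a non-uniform liver (multiplicative log-normal
#' texture) carrying ellipsoidal lesions of the requested volumes and uptake
#' ratios, a soft-tissue body, low-density lungs and a bone insert. The
#' activity map is normalised so its sum equals the configured total
#' activity exactly; everything is deterministic given `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return list with elements `activity` (`voxel_volume`, MBq per voxel),
#'   `density` (`voxel_volume`, g/cm^3) and `vois` (`voi_set`).
#' @export
make_virtual_patient <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- config$grid
  fov <- grid$shape * grid$voxel_size_mm
  if (sum(config$lesion_volumes_mL) >= config$liver_volume_mL)
    stop("requested lesion volumes (", sum(config$lesion_volumes_mL),
         " mL) exceed the liver volume (", config$liver_volume_mL, " mL)")
  with_seed(config$seed, {
    # --- anatomy -----------------------------------------------------------
    # main liver ellipsoid (right-of-centre, mid axial) plus a medial bump
    lv_centre <- c(-0.15 * fov[1], -0.05 * fov[2], 0) +
      stats::rnorm(3, 0, 2)
    ratio <- c(1.25, 1.0, 0.62) * exp(stats::rnorm(3, 0, 0.05))
    liver_main <- ellipsoid_mask_with_volume(grid, lv_centre, ratio,
                                             0.85 * config$liver_volume_mL)
    bump_centre <- lv_centre + c(0.12, 0.10, 0.02) * fov +
      stats::rnorm(3, 0, 2)
    bump <- ellipsoid_mask_with_volume(grid, bump_centre, c(1, 1, 0.7),
                                       0.30 * config$liver_volume_mL)
    liver <- liver_main | bump
    # body, lungs, spine
    body <- ellipsoid_mask(grid, c(0, 0, 0), c(0.46, 0.40, 0.60) * fov)
    body <- body | liver
    lung_z <- c(0.28 * fov[3])
    lungs <- ellipsoid_mask(grid, c(-0.18 * fov[1], 0.05 * fov[2], lung_z),
                            c(0.14, 0.20, 0.22) * fov) |
      ellipsoid_mask(grid, c(0.20 * fov[1], 0.05 * fov[2], lung_z),
                     c(0.13, 0.20, 0.22) * fov)
    lungs <- lungs & body & !liver
    bone <- ellipsoid_mask(grid, c(0, 0.33 * fov[2], 0),
                           c(0.045 * fov[1], 0.045 * fov[2], 0.55 * fov[3]))
    bone <- bone & body & !liver & !lungs
    # --- lesions -----------------------------------------------------------
    lesions <- list()
    occupied <- array(FALSE, grid$shape)
    lv_idx <- which(liver, arr.ind = TRUE)
    ax <- grid_axes_mm(grid)
    for (li in seq_along(config$lesion_volumes_mL)) {
      vol <- config$lesion_volumes_mL[li]
      placed <- FALSE
      sr <- exp(stats::rnorm(3, 0, 0.15)) # mild shape variation
      big <- vol > 0.4 * config$liver_volume_mL
      for (try in 1:300) {
        if (big) {
          # large lesions follow the liver's own shape, near its centre
          ctr <- lv_centre + stats::rnorm(3, 0, 2)
          m <- ellipsoid_mask_with_volume(grid, ctr, ratio, vol)
        } else {
          pick <- lv_idx[sample.int(nrow(lv_idx), 1L), ]
          ctr <- c(ax[[1]][pick[1]], ax[[2]][pick[2]], ax[[3]][pick[3]])
          # as attempts fail, pull candidate centres towards the liver
          # centre (mid-size lesions rarely fit near the liver surface)
          w <- min(0.9, (try - 1) / 150)
          ctr <- (1 - w) * ctr + w * lv_centre
          m <- ellipsoid_mask_with_volume(grid, ctr, sr, vol)
        }
        if (all(liver[m]) && !any(occupied[m])) {
          lesions[[li]] <- m; occupied <- occupied | m; placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("could not place a %.1f mL lesion inside the liver after 300 attempts", vol))
    }
    # --- density -----------------------------------------------------------
    dens <- array(0.0012, grid$shape)
    dens[body] <- config$soft_tissue_density
    dens[lungs] <- config$lung_density
    dens[bone] <- config$bone_density
    # --- activity ----------------------------------------------------------
    tex <- lognormal_texture(grid, liver, config$texture_sigma,
                             config$texture_corr_mm)
    uptake <- array(0, grid$shape)
    uptake[liver] <- 1
    for (li in seq_along(lesions)) uptake[lesions[[li]]] <-
      config$lesion_uptake_ratios[li]
    act <- uptake * tex
    tot <- sum(act)
    if (tot > 0) act <- act * (config$total_activity_GBq * 1000 / tot)
    vois <- voi_set(grid, lesions = lesions, liver = liver, lungs = lungs,
                    bone = bone,
                    background = body & !liver & !lungs & !bone)
    list(activity = voxel_volume(act, grid, "activity_MBq"),
         density = voxel_volume(dens, grid, "density_g_per_cm3"),
         vois = vois)
  })
}

#' Torso-phantom preset
#'
#' A simulated stand-in for a physical torso calibration phantom: a 1200 mL
#' liver background compartment holding a 29 mL ovoid and 16 and 8 mL
#' spherical inserts, lung compartments at lung density and a spine insert at
#' bone density. Default concentrations are 1.3 MBq/mL in the liver
#' background and 7.8/7.7/7.6 MBq/mL in the inserts, chosen at the top of
#' the clinical 6.4-7.8 MBq/mL range so the total activity is 2.0 GBq to
#' within 2% (the printed compartment concentrations and the printed total
#' are not exactly mutually consistent; see the methods vignette).
#' Concentration is uniform within each compartment.
#'
#' @param scale multiplies every activity value (0 gives an all-zero map).
#' @param seed integer seed (insert placement jitter).
#' @param grid a `voxel_grid`.
#' @param insert_conc_MBq_mL concentrations of the three inserts.
#' @param background_conc_MBq_mL liver-minus-inserts concentration.
#' @return list `activity`, `density`, `vois` as in [make_virtual_patient()].
#' @export
make_torso_phantom <- function(scale = 1, seed = 1L, grid = desk_grid(),
                               insert_conc_MBq_mL = c(7.8, 7.7, 7.6),
                               background_conc_MBq_mL = 1.3) {
  stopifnot(scale >= 0)
  with_seed(seed, {
    fov <- grid$shape * grid$voxel_size_mm
    insert_mL <- c(29, 16, 8)
    # liver background region: 1200 mL *excluding* inserts
    liver_bg_mL <- 1200
    lv_centre <- c(-0.12 * fov[1], -0.05 * fov[2], 0)
    liver <- ellipsoid_mask_with_volume(grid, lv_centre, c(1.2, 1.0, 0.65),
                                        liver_bg_mL + sum(insert_mL))
    offs <- list(c(-25, -10, 8), c(22, 8, -6), c(-5, 18, 12))
    shapes <- list(c(1.3, 1.0, 0.8), c(1, 1, 1), c(1, 1, 1)) # ovoid + spheres
    inserts <- list()
    for (i in 1:3) {
      m <- ellipsoid_mask_with_volume(grid, lv_centre + offs[[i]],
                                      shapes[[i]], insert_mL[i])
      if (!all(liver[m])) stop("torso insert ", i, " does not fit inside the liver")
      inserts[[i]] <- m
    }
    body <- ellipsoid_mask(grid, c(0, 0, 0), c(0.46, 0.40, 0.62) * fov) | liver
    lungs <- (ellipsoid_mask(grid, c(-0.18 * fov[1], 0.04 * fov[2], 0.28 * fov[3]),
                             c(0.14, 0.19, 0.22) * fov) |
                ellipsoid_mask(grid, c(0.20 * fov[1], 0.04 * fov[2], 0.28 * fov[3]),
                               c(0.13, 0.19, 0.22) * fov)) & body & !liver
    bone <- ellipsoid_mask(grid, c(0, 0.33 * fov[2], 0),
                           c(0.045 * fov[1], 0.045 * fov[2], 0.55 * fov[3])) &
      body & !liver & !lungs
    dens <- array(0.0012, grid$shape)
    dens[body] <- 1.00
    dens[lungs] <- 0.30
    dens[bone] <- 1.40
    vv <- voxel_volume_mL(grid)
    act <- array(0, grid$shape)
    act[liver] <- background_conc_MBq_mL * vv
    for (i in 1:3) act[inserts[[i]]] <- insert_conc_MBq_mL[i] * vv
    act <- act * scale
    vois <- voi_set(grid, lesions = inserts, liver = liver, lungs = lungs,
                    bone = bone,
                    background = body & !liver & !lungs & !bone)
    list(activity = voxel_volume(act, grid, "activity_MBq"),
         density = voxel_volume(dens, grid, "density_g_per_cm3"),
         vois = vois)
  })
}

#' CT number to mass-density conversion
#'
#' Two-segment piecewise-linear calibration through the anchors
#' (-1000 HU, 0.0012 g/cm^3), (0 HU, 1.000) and (+1000 HU, 1.60); values
#' below -1000 HU clamp to air density and the upper segment extends
#' linearly above +1000 HU. Monotone non-decreasing and non-negative.
#'
#' @param hu a `voxel_volume` of Hounsfield units (quantity "hounsfield" or
#'   "other"), or a bare numeric vector/array.
#' @return matching `voxel_volume` (quantity "density_g_per_cm3") or numeric.
#' @export
ct_to_density <- function(hu) {
  f <- function(h) {
    d <- ifelse(h <= 0, 0.0012 + (h + 1000) * (1.0 - 0.0012) / 1000,
                1.0 + h * 0.60 / 1000)
    pmax(d, 0.0012)
  }
  if (inherits(hu, "voxel_volume")) {
    if (!all(is.finite(hu$values))) stop("ct_to_density: HU values must be finite")
    voxel_volume(f(hu$values), hu$grid, "density_g_per_cm3")
  } else f(hu)
}

#' Density map to linear attenuation map
#'
#' mu = density x (mass-attenuation coefficient of water at the given
#' energy). Used to build the attenuation map entering the SPECT system
#' model; 150 keV (the centre of the 105-195 keV acquisition window) is the
#' conventional effective energy.
#'
#' @param density `voxel_volume` in g/cm^3.
#' @param energy_keV photon energy in [50, 2300] keV.
#' @return `voxel_volume` with quantity "attenuation_per_cm" (1/cm).
#' @export
density_to_attenuation <- function(density, energy_keV = 150) {
  stopifnot(inherits(density, "voxel_volume"))
  mu <- water_mass_attenuation(energy_keV, "total")
  voxel_volume(density$values * mu, density$grid, "attenuation_per_cm")
}
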