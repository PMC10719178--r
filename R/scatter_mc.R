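#' Photon Monte Carlo configuration
#'
#' Settings for the simplified bremsstrahlung photon transport that produces
#' ground-truth scatter and primary projections. The desk-scale default of
#' 2e5 histories is enough for smoke tests; training-quality scatter labels
#' use more histories plus label smoothing (see [make_fixtures()]).
#'
#' @param n_histories photon histories per simulation (>= 1).
#' @param seed integer seed.
#' @param eres_frac_140 Gaussian energy-resolution FWHM fraction at 140 keV
#'   (scales as 1/sqrt(E)).
#' @param half_angle_deg collimator acceptance half-angle.
#' @param cutoff_keV photon termination energy; must lie below the lower
#'   window bound.
#' @param smoothing_fwhm_bins Gaussian smoothing FWHM (in bins) applied
#'   within each view to the scatter mean as a denoised training label;
#'   0 disables.
#' @param smoothing_fwhm_views Gaussian smoothing FWHM across adjacent
#'   views (the scatter mean varies slowly with angle); 0 disables.
#' @export
mc_config <- function(n_histories = 2e5, seed = 1L, eres_frac_140 = 0.095,
                      half_angle_deg = 2, cutoff_keV = 60,
                      smoothing_fwhm_bins = 1, smoothing_fwhm_views = 0) {
  stopifnot(n_histories >= 1, eres_frac_140 >= 0, half_angle_deg > 0,
            cutoff_keV > 0, smoothing_fwhm_bins >= 0,
            smoothing_fwhm_views >= 0)
  structure(list(n_histories = n_histories, seed = as.integer(seed),
                 eres_frac_140 = eres_frac_140,
                 half_angle_deg = half_angle_deg, cutoff_keV = cutoff_keV,
                 smoothing_fwhm_bins = smoothing_fwhm_bins,
                 smoothing_fwhm_views = smoothing_fwhm_views),
            class = "mc_config")
}

#' Monte Carlo scatter and primary projections
#'
#' Runs the analog photon transport (bremsstrahlung emission, Klein-Nishina
#' Compton scattering, photoelectric absorption, Woodcock tracking through
#' the density map, collimator acceptance cone, Gaussian energy blur and
#' 105-195 keV window scoring) and returns separate mean scatter and
#' primary projection sets. Photons with at least one interaction score to
#' scatter, unscattered photons to primary. Outputs are normalised to mean
#' counts per decay and scaled to the map's total activity (counts per
#' second in simulation units, linear in total activity).
#'
#' @param activity `voxel_volume`, MBq per voxel.
#' @param density `voxel_volume`, g/cm^3, same grid.
#' @param geom a [projection_geometry()].
#' @param cfg an [mc_config()].
#' @return list `scatter`, `primary` (`projection_set`s of kinds
#'   "mean_scatter"/"mean_primary") plus `provenance` (seed, histories).
#' @export
simulate_projections <- function(activity, density, geom, cfg = mc_config()) {
  stopifnot(inherits(activity, "voxel_volume"), inherits(density, "voxel_volume"),
            inherits(geom, "projection_geometry"))
  if (!same_grid(activity$grid, density$grid))
    stop("simulate_projections: activity and density grids differ")
  if (sum(activity$values) <= 0)
    stop("simulate_projections: activity map is empty")
  if (cfg$cutoff_keV >= geom$window_keV[1])
    stop("simulate_projections: photon cutoff must lie below the window")
  grid <- activity$grid
  sp <- brems_spectrum()
  res <- with_seed(cfg$seed,
    photon_mc_cpp(activity$values, density$values, grid$shape,
                  grid$voxel_size_mm, grid$origin_mm,
                  geom$angles_deg, geom$nu, geom$nv, geom$pitch_mm,
                  geom$radius_mm,
                  geom$window_keV[1], geom$window_keV[2],
                  cfg$n_histories, cfg$eres_frac_140, cfg$half_angle_deg,
                  cfg$cutoff_keV,
                  sp$energies_keV, sp$cdf,
                  log(.water_mu_energies_keV), log(.water_mu_photo)))
  # counts per decay, scaled to total activity (1 MBq = 1e6 decays/s)
  scale <- sum(activity$values) * 1e6 / cfg$n_histories
  scat <- res$scatter * scale
  prim <- res$primary * scale
  if (cfg$smoothing_fwhm_bins > 0 || cfg$smoothing_fwhm_views > 0) {
    sg <- cfg$smoothing_fwhm_bins / 2.355
    sv <- cfg$smoothing_fwhm_views / 2.355
    scat <- gaussian_smooth3(scat, c(sg, sg, 0))
    if (sv > 0) scat <- gaussian_smooth3(scat, c(0, 0, sv))
  }
  list(scatter = projection_set(scat, geom, "mean_scatter"),
       primary = projection_set(prim, geom, "mean_primary"),
       provenance = list(seed = cfg$seed, n_histories = cfg$n_histories,
                         smoothing_fwhm_bins = cfg$smoothing_fwhm_bins))
}
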