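#' Dose voxel kernel (DVK)
#'
#' 3-D array of dose rate per unit source activity (nGy/s per MBq), centred
#' on the source voxel in water, with odd dimensions along every axis. The
#' kernel extent covers the ~11 mm maximum range of 90Y betas:
#' `K = 2 * round(11 / pitch) + 1` per axis (round half away from zero),
#' which reproduces the 23 x 23 x 13 kernel at 0.98 x 0.98 x 2 mm voxels.
#'
#' @name dose_kernel
NULL

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Kernel dimensions for a voxel size
#' @param voxel_size_mm length-3 voxel pitch.
#' @param range_mm design range (default 11 mm, the 90Y maximum).
#' @return integer triple of odd kernel dimensions.
#' @export
dvk_dimensions <- function(voxel_size_mm, range_mm = 11) {
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3)
  if (any(voxel_size_mm > 2 * range_mm))
    stop("generate_dvk: voxel size larger than ", 2 * range_mm,
         " mm would give a single-voxel kernel")
  as.integer(2 * round_half_away(range_mm / voxel_size_mm) + 1)
}

#' Generate a 90Y dose voxel kernel in water by Monte Carlo
#'
#' Electrons start uniformly within the central voxel of a water volume with
#' isotropic directions and energies from the 90Y beta spectrum, and are
#' transported by condensed-history CSDA (see the methods vignette).
#' Deposited energy is scored per voxel and converted to nGy/s per MBq of
#' source activity (1 MBq = 1e6 decays/s).
#'
#' @param voxel_size_mm kernel voxel pitch (length 3 or scalar).
#' @param n_histories number of electron histories.
#' @param seed integer seed.
#' @param n_batches batches for the per-voxel uncertainty estimate.
#' @return object of class `dose_kernel`: `values` (nGy/s per MBq),
#'   `voxel_size_mm`, `n_histories`, `rel_uncertainty` (per voxel),
#'   `escaped_fraction`, `deposited_MeV_per_decay`, `sampled_MeV_per_decay`.
#' @export
generate_dvk <- function(voxel_size_mm, n_histories = 2e5, seed = 1L,
                         n_batches = 10L) {
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3)
  stopifnot(all(voxel_size_mm > 0), n_histories >= 1)
  dims <- dvk_dimensions(voxel_size_mm)
  bs <- beta_spectrum()
  res <- with_seed(seed, electron_kernel_cpp(dims, voxel_size_mm,
                                             n_histories, as.integer(n_batches),
                                             bs$energies_MeV, bs$cdf))
  mass_kg <- 1.0 * prod(voxel_size_mm / 10) * 1e-3 # water, g -> kg
  # MeV/decay -> nGy/s per MBq: 1.602e-13 J/MeV * 1e6 decays/s * 1e9 nGy/Gy
  conv <- 1.602e-13 * 1e6 * 1e9 / mass_kg
  vals <- res$edep / n_histories * conv
  bm <- res$batches / (n_histories / n_batches) * conv
  mu <- rowMeans(bm)
  se <- apply(bm, 1, stats::sd) / sqrt(n_batches)
  rel <- ifelse(mu > 0, se / mu, 0)
  dim(rel) <- dims
  structure(list(values = vals, voxel_size_mm = voxel_size_mm,
                 n_histories = n_histories, seed = as.integer(seed),
                 rel_uncertainty = rel,
                 escaped_fraction = res$escaped_MeV / res$sampled_MeV,
                 deposited_MeV_per_decay = sum(res$edep) / n_histories,
                 sampled_MeV_per_decay = res$sampled_MeV / n_histories),
            class = "dose_kernel")
}

#' @export
print.dose_kernel <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_kernel %dx%dx%d @ %.3gx%.3gx%.3g mm, %g histories, escape %.2f%%>\n",
              d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2],
              x$voxel_size_mm[3], x$n_histories, 100 * x$escaped_fraction))
  invisible(x)
}

#' Dose-rate map container
#'
#' A `voxel_volume` of dose rate (nGy/s) with a provenance tag recording
#' which dosimetry route produced it (DVK convolution, Monte Carlo, or the
#' residual network) and, for MC maps, a per-voxel relative uncertainty.
#'
#' @param values,grid as in [voxel_volume()].
#' @param provenance one of "DVK", "MC", "network".
#' @param rel_uncertainty optional array of per-voxel relative standard
#'   errors (MC provenance).
#' @export
dose_rate_map <- function(values, grid, provenance, rel_uncertainty = NULL) {
  provenance <- match.arg(provenance, c("DVK", "MC", "network"))
  if (provenance %in% c("DVK", "MC") && any(values < 0))
    stop("dose_rate_map: ", provenance, " dose rates must be non-negative")
  v <- voxel_volume(values, grid, "dose_rate_nGy_per_s")
  v$provenance <- provenance
  v$rel_uncertainty <- rel_uncertainty
  class(v) <- c("dose_rate_map", class(v))
  v
}

#' DVK convolution dosimetry with density scaling and cutoff
#'
#' Zero-padded FFT convolution of the activity map (MBq per voxel) with the
#' dose kernel (nGy/s per MBq), divided voxel-wise by the density (g/cm^3).
#' Voxels with density below the cutoff are set to 0 (the printed rule is a
#' 1.0 g/cm^3 cutoff, which zeroes lung and fat; the threshold is exposed
#' because of that - see the methods vignette).
#'
#' @param activity `voxel_volume` of activity (MBq per voxel).
#' @param kernel a [generate_dvk()] kernel whose voxel sizes match the grid.
#' @param density `voxel_volume` of density on the same grid.
#' @param cutoff_g_cm3 density cutoff (default 1.0).
#' @return a [dose_rate_map()] with provenance "DVK".
#' @export
dvk_convolve <- function(activity, kernel, density, cutoff_g_cm3 = 1.0) {
  stopifnot(inherits(activity, "voxel_volume"), inherits(kernel, "dose_kernel"),
            inherits(density, "voxel_volume"))
  if (!same_grid(activity$grid, density$grid))
    stop("dvk_convolve: activity and density grids differ")
  if (any(abs(kernel$voxel_size_mm - activity$grid$voxel_size_mm) > 1e-6))
    stop("dvk_convolve: kernel voxel size (",
         paste(kernel$voxel_size_mm, collapse = "x"),
         " mm) does not match the activity grid (",
         paste(activity$grid$voxel_size_mm, collapse = "x"),
         " mm); regenerate the kernel rather than resampling")
  d <- activity$grid$shape
  kd <- dim(kernel$values)
  pd <- d + kd - 1L
  A <- array(0, pd); A[1:d[1], 1:d[2], 1:d[3]] <- activity$values
  K <- array(0, pd); K[1:kd[1], 1:kd[2], 1:kd[3]] <- kernel$values
  conv <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / prod(pd)
  ctr <- (kd - 1L) / 2L
  out <- conv[ctr[1] + (1:d[1]), ctr[2] + (1:d[2]), ctr[3] + (1:d[3])]
  out <- pmax(out, 0)
  dens <- density$values
  safe <- pmax(dens, 1e-6)
  out <- out / safe
  out[dens < cutoff_g_cm3] <- 0
  dose_rate_map(out, activity$grid, "DVK")
}

#' Monte Carlo dose-rate map in a heterogeneous medium
#'
#' Decay sites are sampled proportional to the activity map; electrons are
#' transported through the density map (steps consume density-scaled mass
#' pathlength) and deposited energy is converted per voxel mass to nGy/s.
#' The same low-density cutoff rule as [dvk_convolve()] is applied. A
#' batch-based per-voxel relative standard error is attached.
#'
#' @param activity `voxel_volume`, MBq per voxel (sum = total MBq).
#' @param density `voxel_volume`, g/cm^3, same grid.
#' @param n_histories electron histories.
#' @param seed integer seed.
#' @param n_batches uncertainty batches.
#' @param cutoff_g_cm3 density cutoff (default 1.0, as for DVK).
#' @return a [dose_rate_map()] with provenance "MC" and attributes
#'   `escaped_fraction`, `deposited_MeV_per_decay`, `sampled_MeV_per_decay`.
#' @export
mc_dose_rate <- function(activity, density, n_histories = 2e6, seed = 1L,
                         n_batches = 10L, cutoff_g_cm3 = 1.0) {
  stopifnot(inherits(activity, "voxel_volume"), inherits(density, "voxel_volume"))
  if (!same_grid(activity$grid, density$grid))
    stop("mc_dose_rate: activity and density grids differ")
  a_tot <- sum(activity$values)
  if (a_tot <= 0) stop("mc_dose_rate: total activity is zero")
  grid <- activity$grid
  bs <- beta_spectrum()
  res <- with_seed(seed, electron_dose_cpp(activity$values, density$values,
                                           grid$shape, grid$voxel_size_mm,
                                           grid$origin_mm, n_histories,
                                           as.integer(n_batches),
                                           bs$energies_MeV, bs$cdf))
  vol_cm3 <- prod(grid$voxel_size_mm / 10)
  mass_kg <- density$values * vol_cm3 * 1e-3
  safe_mass <- pmax(mass_kg, 1e-12)
  # per-decay MeV -> nGy/s at the phantom's total activity (MBq)
  conv <- 1.602e-13 * 1e6 * 1e9 * a_tot / n_histories
  vals <- res$edep * conv / safe_mass
  bm <- res$batches * (conv * n_batches)
  mu <- rowMeans(bm)
  se <- apply(bm, 1, stats::sd) / sqrt(n_batches)
  rel <- ifelse(mu > 0, se / mu, 0)
  dim(rel) <- grid$shape
  vals[density$values < cutoff_g_cm3] <- 0
  m <- dose_rate_map(vals, grid, "MC", rel_uncertainty = rel)
  m$escaped_fraction <- res$escaped_MeV / res$sampled_MeV
  m$deposited_MeV_per_decay <- sum(res$edep) / n_histories
  m$sampled_MeV_per_decay <- res$sampled_MeV / n_histories
  m
}

#' Convert a dose-rate map to absorbed dose
#'
#' With permanently trapped microspheres the activity only decays, so the
#' absorbed dose is the dose rate at administration times the time integral
#' of the mono-exponential decay: `T_half / ln 2` (in seconds).
#'
#' @param map a `dose_rate_map` (or any `voxel_volume` of a rate).
#' @param half_life_h physical half-life in hours (90Y: 64.1 h).
#' @return `voxel_volume` of absorbed dose (input rate units times seconds).
#' @export
dose_rate_to_dose <- function(map, half_life_h = 64.1) {
  stopifnot(half_life_h > 0)
  factor <- half_life_h * 3600 / log(2)
  voxel_volume(map$values * factor, map$grid, "other")
}

#' Radial energy-deposition profile of a 90Y point source in water
#'
#' Condensed-history MC from a point source in unbounded water, scoring
#' deposited energy into thin spherical shells. Used to measure beta
#' penetration: `beta_max_penetration()` returns the radius enclosing a
#' given fraction of the deposited energy.
#'
#' @param n_histories electron histories (>= 1e5 recommended).
#' @param seed integer seed.
#' @param bin_mm radial bin width.
#' @param max_mm histogram extent.
#' @return list with `radius_mm` (bin upper edges), `energy_MeV` per shell,
#'   `sampled_MeV`, `cumulative_fraction`.
#' @export
beta_range_profile <- function(n_histories = 2e5, seed = 1L, bin_mm = 0.05,
                               max_mm = 15) {
  n_bins <- ceiling(max_mm / bin_mm)
  bs <- beta_spectrum()
  res <- with_seed(seed, electron_radial_cpp(n_histories, bin_mm,
                                             as.integer(n_bins),
                                             bs$energies_MeV, bs$cdf))
  tot <- sum(res$energy_MeV) + res$overflow_MeV
  list(radius_mm = seq_len(n_bins) * bin_mm,
       energy_MeV = as.numeric(res$energy_MeV),
       sampled_MeV = res$sampled_MeV,
       cumulative_fraction = cumsum(res$energy_MeV) / tot)
}

#' Radius enclosing a fraction of deposited energy from a point source
#'
#' @param n_histories,seed passed to [beta_range_profile()].
#' @param fraction energy fraction (default 0.999).
#' @return radius in mm.
#' @export
beta_max_penetration <- function(n_histories = 2e5, seed = 1L,
                                 fraction = 0.999) {
  prof <- beta_range_profile(n_histories, seed)
  prof$radius_mm[which(prof$cumulative_fraction >= fraction)[1]]
}
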