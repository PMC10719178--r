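#' Pipeline configuration
#'
#' Settings for an end-to-end run of the three-stage framework. Exactly one
#' dosimetry arm is selected:
#' \describe{
#'   \item{CNN_SC+DblurDoseNet}{scatter CNN, OS-EM, residual dose network}
#'   \item{CNN_SC+DVK}{scatter CNN, OS-EM, DVK convolution dosimetry}
#'   \item{CNN_SC+MC}{scatter CNN, OS-EM, Monte Carlo dosimetry on the
#'     reconstruction}
#'   \item{noSC+single_stage}{no scatter correction, OS-EM, single-stage
#'     ablation network}
#' }
#'
#' @param arm one of the four arms above.
#' @param seed integer seed (noise/MC stages derive sub-seeds from it).
#' @param efficiency detector efficiency of the system model, in the count
#'   units of the measured projections.
#' @param administered_MBq if given, the reconstruction is globally rescaled
#'   to this total activity (the clinical calibration step).
#' @param osem an [osem_config()].
#' @param cdr a [cdr_model()].
#' @param mc_histories histories for the MC dosimetry arm.
#' @param cutoff_g_cm3 density cutoff for dosimetry.
#' @export
pipeline_config <- function(arm = "CNN_SC+DblurDoseNet", seed = 1L,
                            efficiency = 1, administered_MBq = NULL,
                            osem = osem_config(), cdr = cdr_model(),
                            mc_histories = 2e6, cutoff_g_cm3 = 1.0) {
  arm <- match.arg(arm, c("CNN_SC+DblurDoseNet", "CNN_SC+DVK", "CNN_SC+MC",
                          "noSC+single_stage"))
  structure(list(arm = arm, seed = as.integer(seed), efficiency = efficiency,
                 administered_MBq = administered_MBq, osem = osem, cdr = cdr,
                 mc_histories = mc_histories, cutoff_g_cm3 = cutoff_g_cm3),
            class = "pipeline_config")
}

#' Run the three-stage framework end to end
#'
#' Stage I estimates the scatter projections (CNN arms), stage II performs
#' OS-EM reconstruction with attenuation, scatter mean and CDR, and stage
#' III produces the dose-rate map for the configured arm. Intermediate
#' artifacts (scatter estimate, reconstruction, DVK map) are returned and,
#' when `out_dir` is given, written together with a provenance manifest
#' (seeds, config hash).
#'
#' @param cfg a [pipeline_config()].
#' @param y `projection_set` of measured counts.
#' @param density `voxel_volume` of density on the reconstruction grid.
#' @param scatter_net trained [build_scatter_net()] checkpoint (CNN arms).
#' @param dose_net trained [build_dose_net()] checkpoint (network arms).
#' @param dvk_kernel [generate_dvk()] kernel matching the grid (DVK /
#'   network arms).
#' @param gt_dose optional ground-truth `dose_rate_map` for metrics.
#' @param vois optional [voi_set()] for metrics.
#' @param out_dir optional output directory.
#' @return list with `dose_rate` (a `dose_rate_map`), `recon`,
#'   `scatter_estimate`, `dvk_map`, `manifest`, and `metrics` (when ground
#'   truth was supplied).
#' @export
run_pipeline <- function(cfg, y, density, scatter_net = NULL, dose_net = NULL,
                         dvk_kernel = NULL, gt_dose = NULL, vois = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"), inherits(y, "projection_set"),
            inherits(density, "voxel_volume"))
  stage <- "stage I (scatter estimation)"
  res <- tryCatch({
    mu <- density_to_attenuation(density)
    use_cnn <- cfg$arm != "noSC+single_stage"
    scatter_est <- NULL
    if (use_cnn) {
      if (is.null(scatter_net))
        stop("arm ", cfg$arm, " needs a scatter_net checkpoint")
      att <- project_attenuation(mu, y$geometry)
      scatter_est <- predict_scatter(scatter_net, y, att)
    }
    stage <<- "stage II (OS-EM reconstruction)"
    system <- spect_system(mu, y$geometry, cfg$cdr, cfg$efficiency)
    recon <- osem(y, system, rbar = scatter_est, cfg = cfg$osem)
    if (!is.null(cfg$administered_MBq) && sum(recon$values) > 0)
      recon$values <- recon$values *
        (cfg$administered_MBq / sum(recon$values))
    attr(recon, "scatter_corrected") <- use_cnn
    stage <<- "stage III (dosimetry)"
    dvk_map <- NULL
    if (cfg$arm != "CNN_SC+MC") {
      if (is.null(dvk_kernel))
        stop("arm ", cfg$arm, " needs a DVK kernel")
      dvk_map <- dvk_convolve(recon, dvk_kernel, density, cfg$cutoff_g_cm3)
    }
    dose <- switch(cfg$arm,
      "CNN_SC+DVK" = dvk_map,
      "CNN_SC+MC" = mc_dose_rate(recon, density, cfg$mc_histories,
                                 seed = cfg$seed + 101L,
                                 cutoff_g_cm3 = cfg$cutoff_g_cm3),
      "CNN_SC+DblurDoseNet" = {
        if (is.null(dose_net)) stop("arm needs a dose_net checkpoint")
        if (dose_net$variant != "two_stage")
          stop("arm CNN_SC+DblurDoseNet needs a two-stage checkpoint")
        predict_dose(dose_net, recon, density, dvk_map)
      },
      "noSC+single_stage" = {
        if (is.null(dose_net)) stop("arm needs a dose_net checkpoint")
        if (dose_net$variant != "single_stage")
          stop("arm noSC+single_stage needs a single-stage checkpoint")
        predict_dose(dose_net, recon, density, dvk_map)
      })
    list(dose_rate = dose, recon = recon, scatter_estimate = scatter_est,
         dvk_map = dvk_map)
  }, error = function(e) {
    stop("pipeline aborted in ", stage, ": ", conditionMessage(e),
         call. = FALSE)
  })
  manifest <- list(arm = cfg$arm, seed = cfg$seed,
                   config_hash = config_hash(cfg),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   provenance = res$dose_rate$provenance)
  res$manifest <- manifest
  if (!is.null(gt_dose) && !is.null(vois))
    res$metrics <- metrics_report(gt_dose, res$dose_rate, vois)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$scatter_estimate))
      write_projections(res$scatter_estimate,
                        file.path(out_dir, "scatter_estimate.nii.gz"))
    write_volume(res$recon, file.path(out_dir, "recon.nii.gz"))
    if (!is.null(res$dvk_map))
      write_volume(res$dvk_map, file.path(out_dir, "dvk_map.nii.gz"))
    write_volume(res$dose_rate, file.path(out_dir, "dose_rate.nii.gz"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(res$metrics))
      utils::write.csv(res$metrics, file.path(out_dir, "metrics.csv"),
                       row.names = FALSE)
  }
  res
}

# lesion-volume menus echoing the clinical spread (5.7 - 932 mL)
.fixture_lesion_sets <- list(c(29.6, 27.4, 21.0, 5.7), c(932.1), c(183.8),
                             c(56.9), c(26.4, 8.0), c(21.2, 22.7, 21.7),
                             c(41.8, 12.0), c(150.0, 15.0), c(60.0, 30.0, 10.0),
                             c(300.0, 9.0))

#' Generate the packaged desk-scale virtual-patient fixture set
#'
#' Builds `n` virtual patients with lesion volumes spanning the clinical
#' 5.7-932 mL range and assigns disjoint roles mirroring the train /
#' validate / test discipline used for the two networks: phantoms used to
#' train or validate the scatter network are never reused as its test data,
#' and the dose network trains only on phantoms unseen by it. Regeneration
#' with the same seed is bit-identical.
#'
#' @param seed integer master seed; phantom i uses `seed * 1000 + i`.
#' @param n number of phantoms (default 10).
#' @param grid the shared `voxel_grid`.
#' @param dir optional directory: volumes and a split manifest are written.
#' @return list with `phantoms` (each a [make_virtual_patient()] result
#'   plus `id`, `seed`, `role`) and `manifest` (a tibble).
#' @export
make_fixtures <- function(seed = 1L, n = 10L, grid = desk_grid(), dir = NULL) {
  stopifnot(n >= 3)
  roles <- character(n)
  n_sc <- max(1L, min(round(n * 0.3), n - 2L))
  n_do <- max(1L, min(round(n * 0.3), n - 1L - n_sc))
  roles[seq_len(n_sc)] <- "scatter_trainval"
  roles[n_sc + seq_len(n_do)] <- "dose_trainval"
  roles[roles == ""] <- "test"
  phantoms <- vector("list", n)
  rows <- list()
  for (i in seq_len(n)) {
    les <- .fixture_lesion_sets[[(i - 1) %% length(.fixture_lesion_sets) + 1]]
    pseed <- seed * 1000L + i
    liver <- max(1500, 1.7 * sum(les))
    cfgi <- with_seed(pseed, phantom_config(
      seed = pseed, grid = grid, liver_volume_mL = liver,
      lesion_volumes_mL = les,
      lesion_uptake_ratios = round(stats::runif(length(les), 2, 8), 2),
      total_activity_GBq = round(stats::runif(1, 1.2, 3.0), 2)))
    ph <- make_virtual_patient(cfgi)
    ph$id <- sprintf("vp%02d", i)
    ph$seed <- pseed
    ph$role <- roles[i]
    ph$config <- cfgi
    phantoms[[i]] <- ph
    rows[[i]] <- tibble::tibble(id = ph$id, seed = pseed, role = roles[i],
                                liver_mL = liver,
                                lesion_volumes_mL = paste(les, collapse = ";"),
                                total_activity_GBq = cfgi$total_activity_GBq)
  }
  manifest <- do.call(rbind, rows)
  validate_split(manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (ph in phantoms) {
      write_volume(ph$activity, file.path(dir, paste0(ph$id, "_activity.nii.gz")))
      write_volume(ph$density, file.path(dir, paste0(ph$id, "_density.nii.gz")))
    }
    utils::write.csv(manifest, file.path(dir, "split_manifest.csv"),
                     row.names = FALSE)
  }
  list(phantoms = phantoms, manifest = manifest)
}

#' Validate a fixture split manifest
#'
#' Ensures every phantom has exactly one role, so no network can see its own
#' test phantoms during training.
#'
#' @param manifest the tibble from [make_fixtures()].
#' @export
validate_split <- function(manifest) {
  if (anyDuplicated(manifest$id))
    stop("validate_split: phantom assigned to more than one role")
  need <- c("scatter_trainval", "dose_trainval", "test")
  missing <- setdiff(need, unique(manifest$role))
  if (length(missing))
    stop("validate_split: roles missing from the split: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Simulate a complete SPECT study from a phantom
#'
#' The measurement model used throughout the package's experiments: the
#' scatter mean comes from the photon Monte Carlo (smoothed as a denoised
#' label), the primary mean from the analytic system model scaled to the
#' MC primary total (so the scatter-to-primary ratio is the MC one), and
#' Poisson noise is drawn at the clinical count level.
#'
#' @param phantom a [make_virtual_patient()] / [make_torso_phantom()] result.
#' @param geom a [projection_geometry()].
#' @param cdr a [cdr_model()].
#' @param n_histories photon MC histories.
#' @param seed integer seed (noise uses `seed + 1`).
#' @param target_counts total counts over all views (clinic level ~1e7).
#' @param smoothing_fwhm_bins in-view scatter-label smoothing (FWHM bins).
#' @param smoothing_fwhm_views across-view scatter-label smoothing.
#' @return list with `y` (noisy counts), `att` (attenuation projections),
#'   `scatter_gt` (GT scatter mean in count units), `count_scale`,
#'   `efficiency` (count units per MBq-projection), `mu`, and the phantom.
#' @export
simulate_study <- function(phantom, geom, cdr = cdr_model(),
                           n_histories = 8e6, seed = 1L,
                           target_counts = 1e7, smoothing_fwhm_bins = 8,
                           smoothing_fwhm_views = 4) {
  mu <- density_to_attenuation(phantom$density)
  system <- spect_system(mu, geom, cdr, efficiency = 1)
  sim <- simulate_projections(phantom$activity, phantom$density, geom,
                              mc_config(n_histories = n_histories,
                                        seed = seed,
                                        smoothing_fwhm_bins = smoothing_fwhm_bins,
                                        smoothing_fwhm_views = smoothing_fwhm_views))
  primary_model <- project(phantom$activity, system)
  eff_cal <- sum(sim$primary$values) / max(sum(primary_model$values), 1e-12)
  total_mean <- projection_set(primary_model$values * eff_cal +
                                 sim$scatter$values, geom, "mean_total")
  noisy <- add_poisson_noise(total_mean, target_counts, seed + 1L)
  scatter_gt <- projection_set(sim$scatter$values * noisy$scale, geom,
                               "mean_scatter")
  att <- project_attenuation(mu, geom)
  list(y = noisy$counts, att = att, scatter_gt = scatter_gt,
       count_scale = noisy$scale, efficiency = eff_cal * noisy$scale,
       mu = mu, phantom = phantom)
}
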