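#' OS-EM reconstruction settings
#'
#' @param n_subsets number of ordered subsets (must divide the number of
#'   views; default 4).
#' @param n_iterations full iterations over all subsets (default 16).
#' @param floor_eps clamp applied to the denominator (Ax + rbar) to avoid
#'   0/0 in the multiplicative update.
#' @param log_likelihood if TRUE, record the Poisson log-likelihood after
#'   every full iteration (costs one extra full projection each).
#' @export
osem_config <- function(n_subsets = 4L, n_iterations = 16L,
                        floor_eps = 1e-12, log_likelihood = FALSE) {
  stopifnot(n_subsets >= 1, n_iterations >= 1, floor_eps > 0)
  structure(list(n_subsets = as.integer(n_subsets),
                 n_iterations = as.integer(n_iterations),
                 floor_eps = floor_eps, log_likelihood = log_likelihood),
            class = "osem_config")
}

# interleaved subset view assignment with maximal angular spacing:
# subset s takes views v with (v-1) mod S == offset[s], and the subsets are
# visited in bit-reversal-like order so successive subsets are far apart
subset_views <- function(n_views, n_subsets) {
  if (n_views %% n_subsets != 0)
    stop("osem: number of subsets (", n_subsets,
         ") does not divide the number of views (", n_views, ")")
  offsets <- 0L
  step <- n_subsets
  while (step > 1L) {
    step <- step %/% 2L
    offsets <- c(offsets, offsets + step)
  }
  offsets <- unique(c(offsets, seq_len(n_subsets) - 1L))[seq_len(n_subsets)]
  lapply(offsets, function(o) which((seq_len(n_views) - 1L) %% n_subsets == o))
}

#' Ordered-subsets EM reconstruction with scatter correction
#'
#' Classic OS-EM for the Poisson model y ~ Poisson(A x + rbar): the
#' multiplicative update
#' x <- x * A_s^T( y_s / (A_s x + rbar_s) ) / A_s^T 1
#' cycled over view subsets. With one subset this is exactly MLEM. No
#' post-filter is applied. Iterates are non-negative throughout; voxels with
#' zero sensitivity are excluded (held at 0).
#'
#' @param y `projection_set` of noisy counts.
#' @param system a [spect_system()] (carries mu, CDR, efficiency).
#' @param rbar `projection_set` with the mean scatter (same count units as
#'   `y`), or NULL for no scatter term.
#' @param cfg an [osem_config()].
#' @param x0 optional initial volume; default is a uniform positive image on
#'   the attenuation support (everywhere if mu is zero).
#' @return `voxel_volume` activity estimate (count-rate units of `y`; apply
#'   a global calibration for MBq), with attributes `subset_schedule` and
#'   optionally `log_likelihood`.
#' @export
osem <- function(y, system, rbar = NULL, cfg = osem_config(), x0 = NULL) {
  stopifnot(inherits(y, "projection_set"), inherits(system, "spect_system"))
  geom <- system$geom
  if (!is.null(rbar)) {
    stopifnot(all(dim(rbar$values) == dim(y$values)))
    if (any(rbar$values < 0)) stop("osem: rbar must be non-negative")
    rv <- rbar$values
  } else rv <- array(0, dim(y$values))
  subsets <- subset_views(geom$n_views, cfg$n_subsets)
  d <- system$grid$shape
  # sensitivity images and support
  sens <- lapply(subsets, function(vs)
    backproject(array(1, c(d[1], d[3], length(vs))), system, vs)$values)
  support <- Reduce(`+`, sens) > 0
  if (is.null(x0)) {
    musup <- system$mu$values > 1e-8
    x <- array(0, d)
    x[if (any(musup)) musup else support] <- 1
  } else x <- x0$values
  x[!support] <- 0
  ll <- numeric(0)
  for (it in seq_len(cfg$n_iterations)) {
    for (s in seq_along(subsets)) {
      vs <- subsets[[s]]
      xv <- voxel_volume(x, system$grid, "other")
      fp <- project(xv, system, vs)$values + rv[, , vs, drop = FALSE]
      ratio <- y$values[, , vs, drop = FALSE] / pmax(fp, cfg$floor_eps)
      bp <- backproject(ratio, system, vs)$values
      upd <- bp / pmax(sens[[s]], cfg$floor_eps)
      x <- x * upd
      x[!support] <- 0
    }
    if (cfg$log_likelihood) {
      fp <- project(voxel_volume(x, system$grid, "other"), system)$values + rv
      fp <- pmax(fp, cfg$floor_eps)
      ll <- c(ll, sum(y$values * log(fp) - fp))
    }
  }
  out <- voxel_volume(pmax(x, 0), system$grid, "activity_MBq")
  attr(out, "subset_schedule") <- subsets
  if (cfg$log_likelihood) attr(out, "log_likelihood") <- ll
  out
}

#' Poisson log-likelihood of an activity estimate
#'
#' L(x) = sum_i y_i log((Ax + rbar)_i) - (Ax + rbar)_i. Used as the
#' monotonicity oracle for MLEM.
#'
#' @param x `voxel_volume` activity.
#' @param y `projection_set` counts.
#' @param system a `spect_system`.
#' @param rbar scatter mean (`projection_set` or NULL).
#' @param eps floor inside the log.
#' @export
poisson_log_likelihood <- function(x, y, system, rbar = NULL, eps = 1e-12) {
  fp <- project(x, system)$values
  if (!is.null(rbar)) fp <- fp + rbar$values
  fp <- pmax(fp, eps)
  sum(y$values * log(fp) - fp)
}

#' Resample a reconstruction onto the CT grid
#'
#' Trilinear interpolation onto the CT grid in the shared world frame; for
#' activity the total is preserved by a global rescale (see
#' [resample_volume()]).
#'
#' @param x `voxel_volume` on the SPECT grid.
#' @param ct_grid target `voxel_grid`.
#' @export
resample_to_ct <- function(x, ct_grid) resample_volume(x, ct_grid)
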