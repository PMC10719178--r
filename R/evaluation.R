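#' Normalised mean absolute error (difference of VOI means)
#'
#' `NMAE = |mean(x) - mean(xhat)| / mean(x) * 100` over the mask — the
#' absolute difference of the VOI means relative to the ground-truth mean.
#' Despite its name this is a bias-of-means metric: voxelwise errors that
#' cancel in the mean give 0. The voxelwise counterpart is
#' [voxelwise_mae()].
#'
#' @param x ground-truth `voxel_volume` (or numeric array).
#' @param xhat estimate, same shape.
#' @param mask logical array (default: everything).
#' @return percent (>= 0).
#' @export
nmae <- function(x, xhat, mask = NULL) {
  v <- metric_inputs(x, xhat, mask)
  mx <- mean(v$x)
  if (mx <= 0) stop("nmae: the ground-truth mean over the VOI must be positive")
  abs(mx - mean(v$xhat)) / mx * 100
}

#' Voxelwise mean absolute error (percent of the GT mean)
#'
#' `mean(|x - xhat|) / mean(x) * 100` over the mask. Provided as the
#' voxel-level companion of [nmae()]; not used by any headline comparison.
#'
#' @inheritParams nmae
#' @export
voxelwise_mae <- function(x, xhat, mask = NULL) {
  v <- metric_inputs(x, xhat, mask)
  mx <- mean(v$x)
  if (mx <= 0) stop("voxelwise_mae: the ground-truth mean must be positive")
  mean(abs(v$x - v$xhat)) / mx * 100
}

#' Normalised root-mean-square error
#'
#' `NRMSE = sqrt(mean((x - xhat)^2)) / sqrt(mean(x^2)) * 100` over the mask
#' (RMSE relative to the root-mean-square of the ground truth).
#'
#' @inheritParams nmae
#' @export
nrmse <- function(x, xhat, mask = NULL) {
  v <- metric_inputs(x, xhat, mask)
  rms <- sqrt(mean(v$x^2))
  if (rms <= 0) stop("nrmse: the ground truth is identically zero on the VOI")
  sqrt(mean((v$x - v$xhat)^2)) / rms * 100
}

metric_inputs <- function(x, xhat, mask) {
  xv <- if (inherits(x, "voxel_volume")) x$values else as.array(x)
  ev <- if (inherits(xhat, "voxel_volume")) xhat$values else as.array(xhat)
  stopifnot(all(dim(xv) == dim(ev)))
  if (is.null(mask)) mask <- rep(TRUE, length(xv))
  if (!any(mask)) stop("metric: empty VOI mask")
  list(x = as.numeric(xv[mask]), xhat = as.numeric(ev[mask]))
}

#' Cumulative dose-rate volume histogram (DRVH)
#'
#' For each threshold d, the fraction of the VOI receiving a dose rate of
#' at least d. Fractions start at 1, are non-increasing and end at 0.
#' `d_at(drvh, f)` returns D_f, the largest threshold with coverage >= f
#' (so D10 >= D90 always).
#'
#' @param map `voxel_volume`/`dose_rate_map` (or numeric array).
#' @param mask logical array.
#' @return object of class `drvh` with `thresholds` (ascending) and
#'   `fractions`, plus the sorted VOI values.
#' @export
drvh <- function(map, mask = NULL) {
  mv <- if (inherits(map, "voxel_volume")) map$values else as.array(map)
  if (is.null(mask)) mask <- rep(TRUE, length(mv))
  if (!any(mask)) stop("drvh: empty VOI mask")
  v <- sort(as.numeric(mv[mask]))
  n <- length(v)
  uv <- unique(v)
  # fraction receiving >= each unique threshold
  frac <- 1 - (findInterval(uv, v, left.open = TRUE)) / n
  thr <- c(0, uv, uv[length(uv)] * (1 + 1e-12) + 1e-300)
  fr <- c(1, frac, 0)
  structure(list(thresholds = thr, fractions = fr, sorted_values = v),
            class = "drvh")
}

#' @rdname drvh
#' @param x a `drvh` object.
#' @param f volume fraction in (0, 1]; 0.1 gives D10, 0.9 gives D90.
#' @export
d_at <- function(x, f) {
  stopifnot(inherits(x, "drvh"), f > 0, f <= 1)
  v <- x$sorted_values
  n <- length(v)
  # largest threshold d with fraction(>= d) >= f: the ceiling(f*n)-th
  # largest value
  v[n - ceiling(f * n) + 1]
}

#' @export
print.drvh <- function(x, ...) {
  cat(sprintf("<drvh over %d voxels: D10 = %.4g, D90 = %.4g>\n",
              length(x$sorted_values), d_at(x, 0.1), d_at(x, 0.9)))
  invisible(x)
}

#' Plot a dose-rate volume histogram
#'
#' @param x a [drvh()] (or named list of them for comparison curves).
#' @param xlab x-axis label.
#' @return a ggplot object.
#' @export
plot_drvh <- function(x, xlab = "dose rate (nGy/s)") {
  curves <- if (inherits(x, "drvh")) list(DRVH = x) else x
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    data.frame(method = nm, threshold = cv$thresholds,
               fraction = cv$fractions)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = threshold, y = fraction,
                                   colour = method)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = xlab, y = "fraction of VOI >= dose rate") +
    ggplot2::theme_minimal()
}

#' Lesion-to-background ratio with an automatically placed background VOI
#'
#' The background VOI is the lesion mask translated by an integer voxel
#' offset so that it lies entirely inside the liver, is disjoint from every
#' lesion, and (among the nearest feasible placements within the search
#' radius) minimises the local coefficient of variation of the map - i.e. a
#' nearby uniform liver region of identical size and shape. The ratio is
#' mean(map over lesion) / mean(map over background).
#'
#' @param map `voxel_volume` dose-rate (or activity) map.
#' @param lesion_mask logical array for the target lesion.
#' @param liver_mask logical array for the whole liver.
#' @param all_lesion_masks list of logical arrays (all lesions to avoid).
#' @param search_radius_mm candidate offsets up to this distance (default 50).
#' @param max_candidates cap on the number of feasible placements ranked by
#'   local coefficient of variation (nearest-first ordering).
#' @return list `ratio`, `background_mask`, `offset_voxels`.
#' @export
lesion_to_background <- function(map, lesion_mask, liver_mask,
                                 all_lesion_masks = list(lesion_mask),
                                 search_radius_mm = 50,
                                 max_candidates = 400) {
  mv <- if (inherits(map, "voxel_volume")) map$values else as.array(map)
  grid_vs <- if (inherits(map, "voxel_volume")) map$grid$voxel_size_mm
  else c(1, 1, 1)
  d <- dim(mv)
  idx <- which(lesion_mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("lesion_to_background: empty lesion mask")
  avoid <- Reduce(`|`, all_lesion_masks)
  rng <- floor(search_radius_mm / grid_vs)
  offs <- expand.grid(dx = -rng[1]:rng[1], dy = -rng[2]:rng[2],
                      dz = -rng[3]:rng[3])
  dist <- sqrt((offs$dx * grid_vs[1])^2 + (offs$dy * grid_vs[2])^2 +
                 (offs$dz * grid_vs[3])^2)
  keep <- dist > 0 & dist <= search_radius_mm
  offs <- offs[keep, ]; dist <- dist[keep]
  ord <- order(dist)
  best <- NULL
  n_checked <- 0L
  les_mean <- mean(mv[lesion_mask])
  for (oi in ord) {
    sh <- idx
    sh[, 1] <- sh[, 1] + offs$dx[oi]
    sh[, 2] <- sh[, 2] + offs$dy[oi]
    sh[, 3] <- sh[, 3] + offs$dz[oi]
    if (any(sh < 1) || any(sh[, 1] > d[1]) || any(sh[, 2] > d[2]) ||
        any(sh[, 3] > d[3])) next
    lin <- sh[, 1] + (sh[, 2] - 1) * d[1] + (sh[, 3] - 1) * d[1] * d[2]
    if (!all(liver_mask[lin]) || any(avoid[lin])) next
    vals <- mv[lin]
    m <- mean(vals)
    cv <- if (m > 0) stats::sd(vals) / m else Inf
    if (is.null(best) || cv < best$cv)
      best <- list(cv = cv, lin = lin, off = unlist(offs[oi, ]))
    n_checked <- n_checked + 1L
    if (n_checked >= max_candidates) break
  }
  if (is.null(best))
    stop("lesion_to_background: no feasible background placement within ",
         search_radius_mm, " mm (lesion voxels: ", nrow(idx),
         ", liver voxels: ", sum(liver_mask), ")")
  bg <- array(FALSE, d)
  bg[best$lin] <- TRUE
  list(ratio = les_mean / mean(mv[best$lin]), background_mask = bg,
       offset_voxels = best$off)
}

#' Per-VOI metrics report
#'
#' NMAE and NRMSE per VOI (lesions and healthy liver), as a tibble with one
#' row per VOI, in the layout used for dosimetry comparisons.
#'
#' @param gt ground-truth `voxel_volume`.
#' @param est estimated `voxel_volume`.
#' @param vois a [voi_set()].
#' @param include_liver include a healthy-liver row (default TRUE).
#' @return tibble with columns `voi`, `n_p`, `nmae_pct`, `nrmse_pct`,
#'   `mean_gt`, `mean_est`.
#' @export
metrics_report <- function(gt, est, vois, include_liver = TRUE) {
  rows <- list()
  add <- function(name, mask) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      voi = name, n_p = sum(mask),
      nmae_pct = nmae(gt, est, mask), nrmse_pct = nrmse(gt, est, mask),
      mean_gt = mean(gt$values[mask]), mean_est = mean(est$values[mask]))
  }
  for (i in seq_along(vois$lesions))
    add(sprintf("lesion_%d", i), vois$lesions[[i]])
  if (include_liver && any(vois$healthy_liver))
    add("healthy_liver", vois$healthy_liver)
  do.call(rbind, rows)
}

#' Study-level aggregate of a metrics report
#'
#' @param report a [metrics_report()] tibble (possibly several rbind-ed).
#' @return one-row tibble with mean and sd of NMAE/NRMSE across VOIs.
#' @export
metrics_summary <- function(report) {
  tibble::tibble(n_vois = nrow(report),
                 nmae_mean = mean(report$nmae_pct),
                 nmae_sd = stats::sd(report$nmae_pct),
                 nrmse_mean = mean(report$nrmse_pct),
                 nrmse_sd = stats::sd(report$nrmse_pct))
}
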