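#' Voxel grid geometry
#'
#' An axis-aligned 3-D sampling grid with physical voxel sizes. All volumes,
#' masks and dose maps in the package live on such a grid; world coordinates
#' are millimetres, with `origin_mm` at the corner of voxel (1,1,1) so that
#' the centre of voxel `(i,j,k)` sits at `origin + (c(i,j,k) - 0.5) * voxel_size`.
#'
#' @param shape integer vector of length 3 (nx, ny, nz), all >= 1.
#' @param voxel_size_mm positive numeric vector of length 3, mm per voxel.
#' @param origin_mm numeric vector of length 3; defaults to centring the grid
#'   on the world origin (the rotation isocentre).
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, voxel_size_mm, origin_mm = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  if (is.null(origin_mm)) origin_mm <- -shape * voxel_size_mm / 2
  stopifnot(length(origin_mm) == 3L, all(is.finite(origin_mm)))
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "voxel_grid")
}

#' @export
format.voxel_grid <- function(x, ...) {
  sprintf("<voxel_grid %dx%dx%d @ %.3gx%.3gx%.3g mm>",
          x$shape[1], x$shape[2], x$shape[3],
          x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3])
}

#' @export
print.voxel_grid <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Volume of one voxel in mL (cm^3)
#' @param grid a `voxel_grid`.
#' @return scalar, mL.
#' @export
voxel_volume_mL <- function(grid) prod(grid$voxel_size_mm) / 1000

#' Voxel-centre world coordinates along each axis
#' @keywords internal
grid_axes_mm <- function(grid) {
  lapply(1:3, function(a) {
    grid$origin_mm[a] + (seq_len(grid$shape[a]) - 0.5) * grid$voxel_size_mm[a]
  })
}

same_grid <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) &&
    all(abs(a$voxel_size_mm - b$voxel_size_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

.vv_quantities <- c("activity_MBq", "density_g_per_cm3", "attenuation_per_cm",
                    "dose_rate_nGy_per_s", "hounsfield", "other")

#' 3-D scalar field on a voxel grid
#'
#' The package's basic container: a numeric 3-D array plus its grid and a
#' physical quantity tag. Activity volumes hold MBq *per voxel* (so the array
#' sum is the total activity); density is g/cm^3; attenuation is 1/cm;
#' dose rate is nGy/s (or nGy/s per MBq for kernels).
#'
#' @param values numeric 3-D array matching `grid$shape`.
#' @param grid a `voxel_grid`.
#' @param quantity one of "activity_MBq", "density_g_per_cm3",
#'   "attenuation_per_cm", "dose_rate_nGy_per_s", "hounsfield", "other".
#' @return object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, grid, quantity = "other") {
  quantity <- match.arg(quantity, .vv_quantities)
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3L, all(dim(values) == grid$shape))
  if (!all(is.finite(values))) stop("voxel_volume: values must be finite")
  if (quantity %in% c("activity_MBq", "density_g_per_cm3") && any(values < 0))
    stop("voxel_volume: ", quantity, " values must be non-negative")
  structure(list(values = values, grid = grid, quantity = quantity),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume [%s] %s range [%.4g, %.4g] sum %.6g>\n",
              x$quantity, format(x$grid), min(x$values), max(x$values),
              sum(x$values)))
  invisible(x)
}

#' Total of a volume (e.g. total activity in MBq)
#' @param vol a `voxel_volume`.
#' @export
volume_total <- function(vol) sum(vol$values)

#' Named set of volume-of-interest masks
#'
#' Boolean masks sharing one grid. `healthy_liver` is derived as the liver
#' minus the union of all lesions; this identity is enforced at construction.
#'
#' @param grid a `voxel_grid`.
#' @param lesions list of logical arrays (possibly empty).
#' @param liver,lungs,bone,background logical arrays on `grid` (or NULL).
#' @return object of class `voi_set`.
#' @export
voi_set <- function(grid, lesions = list(), liver = NULL, lungs = NULL,
                    bone = NULL, background = NULL) {
  chk <- function(m, nm) {
    if (is.null(m)) return(array(FALSE, grid$shape))
    stopifnot(is.logical(m), all(dim(m) == grid$shape))
    m
  }
  liver <- chk(liver); lungs <- chk(lungs); bone <- chk(bone)
  background <- chk(background)
  lesions <- lapply(lesions, chk)
  if (length(lesions)) {
    any_lesion <- Reduce(`|`, lesions)
    if (any(any_lesion & !liver))
      stop("voi_set: lesion voxels outside the liver mask")
  } else any_lesion <- array(FALSE, grid$shape)
  structure(list(grid = grid, lesions = lesions, liver = liver,
                 healthy_liver = liver & !any_lesion,
                 lungs = lungs, bone = bone, background = background),
            class = "voi_set")
}

#' Mask volume in mL
#' @param mask logical array.
#' @param grid the `voxel_grid` the mask lives on.
#' @export
mask_volume_mL <- function(mask, grid) sum(mask) * voxel_volume_mL(grid)

#' Trilinear resampling of a volume onto another grid
#'
#' Values are interpolated in world coordinates (constant fields are
#' reproduced exactly). For activity volumes the per-voxel amounts are first
#' converted to concentrations, interpolated, converted back, and finally
#' rescaled globally so the total activity is preserved exactly.
#'
#' @param vol a `voxel_volume`.
#' @param grid target `voxel_grid` (same world frame).
#' @return `voxel_volume` on `grid`.
#' @export
resample_volume <- function(vol, grid) {
  src <- vol$grid
  # overlap check in world coordinates
  lo_s <- src$origin_mm; hi_s <- src$origin_mm + src$shape * src$voxel_size_mm
  lo_t <- grid$origin_mm; hi_t <- grid$origin_mm + grid$shape * grid$voxel_size_mm
  if (any(hi_t <= lo_s) || any(lo_t >= hi_s))
    stop("resample_volume: grids do not overlap")
  vals <- vol$values
  conc <- vol$quantity == "activity_MBq"
  if (conc) vals <- vals / voxel_volume_mL(src)
  ax_t <- grid_axes_mm(grid)
  # fractional source voxel-centre index per target axis (1-based)
  fi <- lapply(1:3, function(a)
    (ax_t[[a]] - src$origin_mm[a]) / src$voxel_size_mm[a] + 0.5)
  out <- trilinear_sample(vals, fi[[1]], fi[[2]], fi[[3]])
  if (conc) {
    out <- out * voxel_volume_mL(grid)
    tot_in <- sum(vol$values); tot_out <- sum(out)
    if (tot_in > 0 && tot_out > 0) out <- out * (tot_in / tot_out)
  }
  voxel_volume(out, grid, vol$quantity)
}

# sample a 3-D array at the outer product of fractional indices (1-based,
# clamped to the edge so constants extend beyond the border)
trilinear_sample <- function(arr, ix, iy, iz) {
  d <- dim(arr)
  part <- function(f, n) {
    f <- pmin(pmax(f, 1), n)
    i0 <- pmin(floor(f), n - 1L); if (n == 1L) i0 <- rep(1, length(f))
    w <- f - i0
    list(i0 = as.integer(i0), i1 = as.integer(pmin(i0 + 1, n)), w = w)
  }
  px <- part(ix, d[1]); py <- part(iy, d[2]); pz <- part(iz, d[3])
  out <- array(0, c(length(ix), length(iy), length(iz)))
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    wx <- if (bx == 0) 1 - px$w else px$w
    wy <- if (by == 0) 1 - py$w else py$w
    wz <- if (bz == 0) 1 - pz$w else pz$w
    sub <- arr[if (bx == 0) px$i0 else px$i1,
               if (by == 0) py$i0 else py$i1,
               if (bz == 0) pz$i0 else pz$i1, drop = FALSE]
    w <- outer(outer(wx, wy), wz)
    out <- out + sub * w
  }
  out
}

#' Box down-sampling by an integer factor
#'
#' Averages non-overlapping `factor^3` blocks. Used as the adjoint-flavoured
#' counterpart of up-sampling in resampling round-trip checks.
#'
#' @param vol a `voxel_volume` whose shape is divisible by `factor`.
#' @param factor positive integer.
#' @export
downsample_box <- function(vol, factor = 2L) {
  factor <- as.integer(factor)
  d <- vol$grid$shape
  stopifnot(all(d %% factor == 0L))
  nd <- d %/% factor
  v <- vol$values
  dim(v) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  out <- apply(v, c(2, 4, 6), mean)
  g <- voxel_grid(nd, vol$grid$voxel_size_mm * factor, vol$grid$origin_mm)
  vals <- if (vol$quantity == "activity_MBq") out * factor^3 else out
  voxel_volume(vals, g, vol$quantity)
}

# run expr with a fixed RNG seed, restoring the caller's RNG state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
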