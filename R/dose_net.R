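#' Residual dose-network architecture
#'
#' Slice-pack residual network for dose-rate estimation: packs of
#' `pack_depth` adjacent scaled-activity and density slices are stacked as
#' two channels, passed to a 3-layer 3-D convolutional feature extractor
#' whose axial kernel depths collapse the pack to the middle slice, then to
#' a 2-D U-Net. The DVK dose-rate slice is added to the U-Net output
#' (residual learning) and the terminal transform applies density
#' correction and inverse scaling. The final residual convolution is
#' zero-initialised, so the untrained network reproduces DVK dosimetry
#' exactly.
#'
#' @param pack_depth odd number of slices per input pack (default 11).
#' @param extractor_kernel in-plane kernel of the 3-D extractor (default 7).
#' @param extractor_depths axial kernel depths of the three 3-D
#'   convolutions; must satisfy `sum(depths - 1) == pack_depth - 1`. The
#'   default (5, 5, 3) follows the architecture figure; (5, 3, 3) with a
#'   9-slice pack is the text variant.
#' @param extractor_channels feature channels of the extractor.
#' @param unet_levels resolution levels of the 2-D U-Net (default 4).
#' @param unet_base channels at the finest level (doubled per level,
#'   default 32).
#' @export
dose_net_spec <- function(pack_depth = 11L, extractor_kernel = 7L,
                          extractor_depths = c(5L, 5L, 3L),
                          extractor_channels = 16L,
                          unet_levels = 4L, unet_base = 32L) {
  pack_depth <- as.integer(pack_depth)
  if (pack_depth %% 2 == 0) stop("dose_net_spec: pack depth must be odd")
  extractor_depths <- as.integer(extractor_depths)
  if (sum(extractor_depths - 1L) != pack_depth - 1L)
    stop("dose_net_spec: axial depths ", paste(extractor_depths, collapse = ","),
         " do not collapse a ", pack_depth, "-slice pack to one slice")
  structure(list(pack_depth = pack_depth,
                 extractor_kernel = as.integer(extractor_kernel),
                 extractor_depths = extractor_depths,
                 extractor_channels = as.integer(extractor_channels),
                 unet_levels = as.integer(unet_levels),
                 unet_base = as.integer(unet_base)),
            class = "dose_net_spec")
}

#' Build (initialise) the residual dose network
#'
#' @param spec a [dose_net_spec()].
#' @param seed integer seed.
#' @param variant "two_stage" (inputs are scatter-corrected reconstructions)
#'   or "single_stage" (the ablation variant taking no-SC reconstructions).
#' @return object of class `dose_net`; untrained output is identically the
#'   DVK dose-rate map (zero-initialised residual head).
#' @export
build_dose_net <- function(spec, seed = 1L, variant = "two_stage") {
  stopifnot(inherits(spec, "dose_net_spec"))
  variant <- match.arg(variant, c("two_stage", "single_stage"))
  k <- spec$extractor_kernel; ec <- spec$extractor_channels
  L <- spec$unet_levels; base <- spec$unet_base
  with_seed(seed, {
    ext <- list(conv3d_params(k, k, spec$extractor_depths[1], 2, ec),
                conv3d_params(k, k, spec$extractor_depths[2], ec, ec),
                conv3d_params(k, k, spec$extractor_depths[3], ec, ec))
    ch <- base * 2^(seq_len(L) - 1)
    enc <- vector("list", L)
    cin <- ec
    for (l in seq_len(L)) {
      enc[[l]] <- list(conv2d_params(3, 3, cin, ch[l]),
                       conv2d_params(3, 3, ch[l], ch[l]))
      cin <- ch[l]
    }
    dec <- vector("list", max(L - 1, 0))
    for (l in rev(seq_len(L - 1))) {
      dec[[l]] <- list(conv2d_params(3, 3, ch[l + 1] + ch[l], ch[l]),
                       conv2d_params(3, 3, ch[l], ch[l]))
    }
    head <- conv2d_params(3, 3, ch[1], 1, zero = TRUE)
    structure(list(spec = spec,
                   params = list(ext = ext, enc = enc, dec = dec, head = head),
                   seed = as.integer(seed), variant = variant,
                   scaled_mean = 1, d_scale = 1, density_floor = 0.3,
                   trained = FALSE),
              class = "dose_net")
  })
}

# forward through extractor + U-Net; packs are (H, W, D) arrays already
# scaled. Returns residual slice (H, W, 1) and optional cache.
dose_net_fwd <- function(net, act_pack, den_pack, keep = FALSE) {
  p <- net$params
  d <- dim(act_pack)
  x3 <- array(c(act_pack, den_pack), c(d[1], d[2], d[3], 2L))
  exs <- list(); eys <- list()
  x <- x3
  for (i in seq_along(p$ext)) {
    exs[[i]] <- x
    y <- relu_f(conv3d_f(x, p$ext[[i]]))
    eys[[i]] <- y
    x <- y
  }
  x <- array(x, dim(x)[c(1, 2, 4)]) # depth collapsed to 1
  L <- net$spec$unet_levels
  skips <- list(); encc <- list()
  for (l in seq_len(L)) {
    c1 <- p$enc[[l]][[1]]; c2 <- p$enc[[l]][[2]]
    x1 <- x
    y1 <- relu_f(conv2d_f(x1, c1))
    y2 <- relu_f(conv2d_f(y1, c2))
    encc[[l]] <- list(x1 = x1, y1 = y1, y2 = y2)
    skips[[l]] <- y2
    if (l < L) x <- pool2_f(y2)
  }
  x <- skips[[L]]
  decc <- list()
  for (l in rev(seq_len(L - 1))) {
    up <- upsample2_f(x)
    xc <- concat_ch(up, skips[[l]])
    c1 <- p$dec[[l]][[1]]; c2 <- p$dec[[l]][[2]]
    y1 <- relu_f(conv2d_f(xc, c1))
    y2 <- relu_f(conv2d_f(y1, c2))
    decc[[as.character(l)]] <- list(up = up, xc = xc, y1 = y1, y2 = y2,
                                    xin_dim = dim(x))
    x <- y2
  }
  res <- conv2d_f(x, p$head)
  if (!keep) return(res)
  list(res = res, x3 = x3, exs = exs, eys = eys, encc = encc, decc = decc,
       last = x)
}

dose_net_bwd <- function(net, cache, gres) {
  p <- net$params
  L <- net$spec$unet_levels
  hb <- conv2d_b(cache$last, p$head, gres)
  g_head <- list(w = hb$gw, b = hb$gb)
  g <- hb$gx
  g_dec <- vector("list", max(L - 1, 0))
  g_skip <- vector("list", L)
  # walk the decoder from the finest block (processed last in the forward
  # pass) back up to the coarsest
  for (l in seq_len(L - 1)) {
    cc <- cache$decc[[as.character(l)]]
    g2 <- relu_b(cc$y2, g)
    b2 <- conv2d_b(cc$y1, p$dec[[l]][[2]], g2)
    g1 <- relu_b(cc$y1, b2$gx)
    b1 <- conv2d_b(cc$xc, p$dec[[l]][[1]], g1)
    g_dec[[l]] <- list(list(w = b1$gw, b = b1$gb), list(w = b2$gw, b = b2$gb))
    nup <- dim(cc$up)[3]
    gup <- b1$gx[, , seq_len(nup), drop = FALSE]
    g_skip[[l]] <- b1$gx[, , nup + seq_len(dim(b1$gx)[3] - nup), drop = FALSE]
    g <- upsample2_b(gup)
  }
  # g now flows into skips[[L]] (the bottleneck output)
  g_enc <- vector("list", L)
  gx_net <- NULL
  for (l in rev(seq_len(L))) {
    cc <- cache$encc[[l]]
    gtot <- if (l == L) g else {
      gp <- pool2_b(gdown, dim(cc$y2))
      gp + (if (is.null(g_skip[[l]])) 0 else g_skip[[l]])
    }
    g2 <- relu_b(cc$y2, gtot)
    b2 <- conv2d_b(cc$y1, p$enc[[l]][[2]], g2)
    g1 <- relu_b(cc$y1, b2$gx)
    b1 <- conv2d_b(cc$x1, p$enc[[l]][[1]], g1)
    g_enc[[l]] <- list(list(w = b1$gw, b = b1$gb), list(w = b2$gw, b = b2$gb))
    gdown <- b1$gx
  }
  g <- gdown # gradient wrt extractor output (H, W, C)
  dim(g) <- c(dim(g)[1], dim(g)[2], 1L, dim(g)[3])
  g_ext <- vector("list", length(p$ext))
  for (i in rev(seq_along(p$ext))) {
    g <- relu_b(cache$eys[[i]], g)
    bb <- conv3d_b(cache$exs[[i]], p$ext[[i]], g)
    g_ext[[i]] <- list(w = bb$gw, b = bb$gb)
    g <- bb$gx
  }
  list(ext = g_ext, enc = g_enc, dec = g_dec, head = g_head)
}

# clamp-replicated slice pack around z
slice_pack <- function(values, z, depth) {
  nz <- dim(values)[3]
  half <- (depth - 1L) / 2L
  idx <- pmin(pmax(z + seq(-half, half), 1L), nz)
  values[, , idx, drop = FALSE]
}

# terminal transform: residual in scaled units -> dose-rate slice
dose_net_output <- function(net, res, dvk_slice, den_slice) {
  dvk_slice + (res[, , 1] * net$d_scale) / pmax(den_slice, net$density_floor)
}

dose_val_mse <- function(net, samples) {
  mean(vapply(samples, function(sm) {
    res <- dose_net_fwd(net, sm$act, sm$den, keep = FALSE)
    out <- dose_net_output(net, res, sm$dvk, sm$den_mid)
    mean((out - sm$gt)^2)
  }, numeric(1)))
}

# per-study activity scale: scaled voxels have mean `scaled_mean`, i.e.
# they sum to scaled_mean * n_voxels (a grid-size-independent normalising
# constant)
activity_scale <- function(net, activity) {
  net$scaled_mean * length(activity$values) / max(sum(activity$values), 1e-12)
}

dose_samples <- function(net, studies, slice_stride = 1L) {
  out <- list()
  depth <- net$spec$pack_depth
  for (s in studies) {
    sa <- activity_scale(net, s$activity)
    nz <- s$activity$grid$shape[3]
    for (z in seq(1L, nz, by = slice_stride)) {
      out[[length(out) + 1]] <- list(
        act = slice_pack(s$activity$values, z, depth) * sa,
        den = slice_pack(s$density$values, z, depth),
        dvk = s$dvk$values[, , z],
        den_mid = s$density$values[, , z],
        gt = s$gt$values[, , z])
    }
  }
  out
}

#' Train the residual dose network
#'
#' Minimises pixel-wise MSE between the network's dose-rate slices and the
#' ground-truth MC dose-rate maps. Slices cover all axial positions (with
#' replicate padding at the ends, optionally strided); the best-validation
#' checkpoint is retained. Ground-truth labels must come from the true
#' activity/density MC route (provenance "MC"), never from reconstructions.
#'
#' @param net a [build_dose_net()] network.
#' @param studies list of studies: `activity` (reconstruction on the CT
#'   grid), `density`, `dvk` (DVK dose-rate map of that reconstruction),
#'   `gt` (MC dose-rate map of the true phantom), co-registered on one grid.
#' @param cfg a [train_config()].
#' @param val_studies held-out studies (default: last study of `studies`).
#' @param slice_stride train on every `slice_stride`-th axial slice.
#' @return trained `dose_net` with `history` (epoch 0 is the DVK baseline).
#' @export
train_dose_net <- function(net, studies, cfg = train_config(lr = 1e-3),
                           val_studies = NULL, slice_stride = 1L) {
  stopifnot(inherits(net, "dose_net"), length(studies) >= 1)
  for (s in studies) {
    if (!identical(s$gt$provenance, "MC"))
      stop("train_dose_net: ground-truth labels must be MC dose-rate maps")
    if (!same_grid(s$activity$grid, s$gt$grid))
      stop("train_dose_net: study volumes are not co-registered")
  }
  if (is.null(val_studies)) {
    if (length(studies) > 1) {
      val_studies <- studies[length(studies)]
      studies <- studies[-length(studies)]
    } else val_studies <- studies
  }
  # residual unit: RMS of the (GT - DVK) discrepancy over the training set
  resid <- unlist(lapply(studies, function(s) {
    w <- s$gt$values > 0
    (s$gt$values - s$dvk$values)[w]
  }))
  net$d_scale <- max(sqrt(mean(resid^2)), 1e-12)
  tr <- dose_samples(net, studies, slice_stride)
  va <- dose_samples(net, val_studies, slice_stride)
  state <- adam_init(net$params)
  val0 <- dose_val_mse(net, va)
  hist <- data.frame(epoch = 0L, train_loss = NA_real_, val_mse = val0)
  best <- list(params = net$params, val = val0)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(tr))
      ep_loss <- 0
      bi <- 0
      while (bi < length(ord)) {
        idx <- ord[(bi + 1):min(bi + cfg$batch_size, length(ord))]
        bi <- bi + length(idx)
        gacc <- NULL
        for (i in idx) {
          sm <- tr[[i]]
          cc <- dose_net_fwd(net, sm$act, sm$den, keep = TRUE)
          out <- dose_net_output(net, cc$res, sm$dvk, sm$den_mid)
          diff <- out - sm$gt
          ep_loss <- ep_loss + mean(diff^2)
          gres <- 2 * diff / length(diff) * net$d_scale /
            pmax(sm$den_mid, net$density_floor)
          dim(gres) <- c(dim(gres), 1L)
          gr <- dose_net_bwd(net, cc, gres)
          gacc <- if (is.null(gacc)) gr else nn_axpy(1, gr, gacc)
        }
        if (cfg$lr > 0) {
          gacc <- rapply(gacc, function(a) a / length(idx), how = "replace")
          st <- adam_step(net$params, gacc, state, cfg$lr)
          net$params <- st$params
          state <- st$state
        }
      }
      vm <- dose_val_mse(net, va)
      hist <- rbind(hist, data.frame(epoch = ep,
                                     train_loss = ep_loss / length(tr),
                                     val_mse = vm))
      if (vm < best$val) best <- list(params = net$params, val = vm)
    }
  })
  net$params <- best$params
  net$trained <- TRUE
  net$history <- hist
  net
}

#' Predict a dose-rate map with the residual network
#'
#' Slice-by-slice inference with replicate-padded packs, reassembled into a
#' volume. Negative outputs are clamped to 0; the clamped fraction is
#' recorded in the result's `clamped_fraction` element.
#'
#' @param net a `dose_net`.
#' @param activity reconstruction (`voxel_volume`) on the CT grid. For a
#'   single-stage checkpoint this must be a no-SC reconstruction (guarded
#'   via the volume's `scatter_corrected` attribute when present).
#' @param density `voxel_volume` of density, same grid.
#' @param dvk_map [dvk_convolve()] dose-rate map of `activity`, same grid.
#' @return a [dose_rate_map()] with provenance "network".
#' @export
predict_dose <- function(net, activity, density, dvk_map) {
  stopifnot(inherits(net, "dose_net"))
  if (missing(density) || is.null(density))
    stop("predict_dose: a density volume is required")
  if (!same_grid(activity$grid, density$grid) ||
      !same_grid(activity$grid, dvk_map$grid))
    stop("predict_dose: volumes are not co-registered")
  sc <- attr(activity, "scatter_corrected")
  if (net$variant == "single_stage" && isTRUE(sc))
    stop("predict_dose: single-stage checkpoint expects a no-SC reconstruction")
  sa <- activity_scale(net, activity)
  d <- activity$grid$shape
  out <- array(0, d)
  for (z in seq_len(d[3])) {
    ap <- slice_pack(activity$values, z, net$spec$pack_depth) * sa
    dp <- slice_pack(density$values, z, net$spec$pack_depth)
    res <- dose_net_fwd(net, ap, dp)
    out[, , z] <- dose_net_output(net, res, dvk_map$values[, , z],
                                  density$values[, , z])
  }
  neg <- mean(out < 0)
  out[out < 0] <- 0
  m <- dose_rate_map(out, activity$grid, "network")
  m$clamped_fraction <- neg
  m
}
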