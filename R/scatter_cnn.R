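#' Scatter network architecture
#'
#' Two-branch projection-space CNN: the scaled total projection and the
#' projected attenuation map each pass through `branch_layers` 3x3
#' convolution + ReLU layers, are concatenated along channels, pass through
#' `trunk_layers` further 3x3 conv + ReLU layers, and end in a pointwise
#' (1x1) convolution followed by a terminal ReLU, so the scatter estimate is
#' non-negative by construction. All convolutions use zero padding 1, so the
#' spatial size (e.g. 128 x 80) is preserved through every layer.
#'
#' @param input_shape detector size c(nu, nv).
#' @param branch_channels channels in each input branch (default 16).
#' @param trunk_channels channels in the trunk (default 32).
#' @param branch_layers,trunk_layers convolution counts (default 3 each).
#' @param kernel in-plane kernel size (default 3).
#' @export
scatter_net_spec <- function(input_shape, branch_channels = 16L,
                             trunk_channels = 32L, branch_layers = 3L,
                             trunk_layers = 3L, kernel = 3L) {
  stopifnot(length(input_shape) == 2, branch_layers >= 1, trunk_layers >= 1,
            kernel %% 2 == 1)
  structure(list(input_shape = as.integer(input_shape),
                 branch_channels = as.integer(branch_channels),
                 trunk_channels = as.integer(trunk_channels),
                 branch_layers = as.integer(branch_layers),
                 trunk_layers = as.integer(trunk_layers),
                 kernel = as.integer(kernel)),
            class = "scatter_net_spec")
}

#' Build (initialise) the scatter network
#'
#' He-normal initialisation, deterministic given `seed`.
#'
#' @param spec a [scatter_net_spec()].
#' @param seed integer seed.
#' @return object of class `scatter_net`.
#' @export
build_scatter_net <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scatter_net_spec"))
  k <- spec$kernel; bc <- spec$branch_channels; tc <- spec$trunk_channels
  with_seed(seed, {
    branch <- function() {
      out <- list(conv2d_params(k, k, 1, bc))
      for (i in seq_len(spec$branch_layers - 1))
        out[[i + 1]] <- conv2d_params(k, k, bc, bc)
      out
    }
    trunk <- list(conv2d_params(k, k, 2 * bc, tc))
    for (i in seq_len(spec$trunk_layers - 1))
      trunk[[i + 1]] <- conv2d_params(k, k, tc, tc)
    params <- list(proj_branch = branch(), att_branch = branch(),
                   trunk = trunk, head = conv2d_params(1, 1, tc, 1))
    structure(list(spec = spec, params = params, seed = as.integer(seed),
                   att_divisor = 10, count_scale_const = 1e-4,
                   trained = FALSE),
              class = "scatter_net")
  })
}

# forward pass on one view; inputs already scaled. Returns output and,
# optionally, the cache needed for backprop.
scatter_net_fwd <- function(net, pin, ain, keep = FALSE) {
  p <- net$params
  run_branch <- function(lays, x) {
    xs <- list(); ys <- list()
    for (i in seq_along(lays)) {
      xs[[i]] <- x
      y <- relu_f(conv2d_f(x, lays[[i]]))
      ys[[i]] <- y
      x <- y
    }
    list(out = x, xs = xs, ys = ys)
  }
  d <- dim(pin)
  if (is.null(d) || length(d) == 2) { dim(pin) <- c(dim(pin), 1L); dim(ain) <- dim(pin) }
  bp <- run_branch(p$proj_branch, pin)
  ba <- run_branch(p$att_branch, ain)
  xc <- concat_ch(bp$out, ba$out)
  tr <- run_branch(p$trunk, xc)
  hz <- conv2d_f(tr$out, p$head)
  out <- relu_f(hz)
  if (!keep) return(out)
  list(out = out, bp = bp, ba = ba, xc = xc, tr = tr, hz = hz)
}

# backward pass; g is dLoss/dOut. Returns gradient list mirroring params.
scatter_net_bwd <- function(net, cache, g) {
  p <- net$params
  back_branch <- function(lays, cc, g) {
    gl <- vector("list", length(lays))
    for (i in rev(seq_along(lays))) {
      g <- relu_b(cc$ys[[i]], g)
      bw <- conv2d_b(cc$xs[[i]], lays[[i]], g)
      gl[[i]] <- list(w = bw$gw, b = bw$gb)
      g <- bw$gx
    }
    list(grads = gl, gx = g)
  }
  g <- relu_b(cache$out, g)
  hb <- conv2d_b(cache$tr$out, p$head, g)
  g_head <- list(w = hb$gw, b = hb$gb)
  tb <- back_branch(p$trunk, cache$tr, hb$gx)
  bc <- net$spec$branch_channels
  gp <- tb$gx[, , seq_len(bc), drop = FALSE]
  ga <- tb$gx[, , bc + seq_len(bc), drop = FALSE]
  pb <- back_branch(p$proj_branch, cache$bp, gp)
  ab <- back_branch(p$att_branch, cache$ba, ga)
  list(proj_branch = pb$grads, att_branch = ab$grads, trunk = tb$grads,
       head = g_head)
}

# per-study input scaling: the total projection (and the scatter label) are
# divided by total counts * 1e-4; the attenuation projection by 10
scatter_scale_factor <- function(net, y_values) {
  tot <- sum(y_values)
  if (tot <= 0) return(1)
  1 / (tot * net$count_scale_const)
}

# assemble per-view training samples from studies
scatter_samples <- function(net, studies) {
  out <- list()
  for (s in studies) {
    fs <- scatter_scale_factor(net, s$y$values)
    for (v in seq_len(dim(s$y$values)[3])) {
      out[[length(out) + 1]] <- list(
        pin = array(s$y$values[, , v] * fs, c(dim(s$y$values)[1:2], 1L)),
        ain = array(s$att$values[, , v] / net$att_divisor,
                    c(dim(s$y$values)[1:2], 1L)),
        tgt = array(s$scatter$values[, , v] * fs,
                    c(dim(s$y$values)[1:2], 1L)))
    }
  }
  out
}

scatter_val_mse <- function(net, samples) {
  mean(vapply(samples, function(sm) {
    out <- scatter_net_fwd(net, sm$pin, sm$ain)
    mean((out - sm$tgt)^2)
  }, numeric(1)))
}

#' Train the scatter network
#'
#' Minimises pixel-wise MSE between estimated and ground-truth (MC) scatter
#' projections in the scaled input domain, with Adam. One or more studies
#' are held out for validation; the best-validation parameters are retained.
#'
#' @param net a [build_scatter_net()] network.
#' @param studies list of studies, each a list with `y` (total noisy counts,
#'   `projection_set`), `att` (attenuation line integrals) and `scatter`
#'   (GT scatter mean in the same count units as `y`).
#' @param cfg a [train_config()].
#' @param val_studies list of studies for validation (default: the last
#'   study of `studies` is held out).
#' @param augment apply random horizontal/axial flips to training samples
#'   (mirror-image studies are equally valid physics, so flips enlarge the
#'   effective training diversity; validation is never augmented).
#' @return the trained `scatter_net` with a `history` element (per-epoch
#'   train loss and validation MSE; entry 1 is the untrained validation).
#' @export
train_scatter_net <- function(net, studies, cfg = train_config(),
                              val_studies = NULL, augment = TRUE) {
  stopifnot(inherits(net, "scatter_net"), length(studies) >= 1)
  if (is.null(val_studies)) {
    if (length(studies) > 1) {
      val_studies <- studies[length(studies)]
      studies <- studies[-length(studies)]
    } else val_studies <- studies
  }
  tr <- scatter_samples(net, studies)
  va <- scatter_samples(net, val_studies)
  if (!length(tr)) stop("train_scatter_net: empty training set")
  state <- adam_init(net$params)
  val0 <- scatter_val_mse(net, va)
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
          if (augment) {
            if (stats::runif(1) < 0.5) {
              sm$pin <- sm$pin[dim(sm$pin)[1]:1, , , drop = FALSE]
              sm$ain <- sm$ain[dim(sm$ain)[1]:1, , , drop = FALSE]
              sm$tgt <- sm$tgt[dim(sm$tgt)[1]:1, , , drop = FALSE]
            }
            if (stats::runif(1) < 0.5) {
              sm$pin <- sm$pin[, dim(sm$pin)[2]:1, , drop = FALSE]
              sm$ain <- sm$ain[, dim(sm$ain)[2]:1, , drop = FALSE]
              sm$tgt <- sm$tgt[, dim(sm$tgt)[2]:1, , drop = FALSE]
            }
          }
          cc <- scatter_net_fwd(net, sm$pin, sm$ain, keep = TRUE)
          diff <- cc$out - sm$tgt
          ep_loss <- ep_loss + mean(diff^2)
          g <- 2 * diff / length(diff)
          gr <- scatter_net_bwd(net, cc, g)
          gacc <- if (is.null(gacc)) gr else nn_axpy(1, gr, gacc)
        }
        if (cfg$lr > 0) {
          gacc <- rapply(gacc, function(a) a / length(idx), how = "replace")
          st <- adam_step(net$params, gacc, state, cfg$lr)
          net$params <- st$params
          state <- st$state
        }
      }
      vm <- scatter_val_mse(net, va)
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

#' Predict scatter projections for a study
#'
#' Scales the inputs exactly as during training, runs the network view by
#' view, and rescales the output back to count units.
#'
#' @param net a trained (or untrained) `scatter_net`.
#' @param y `projection_set` of total measured counts.
#' @param att `projection_set` of attenuation line integrals.
#' @param flip_average symmetrised inference: average the predictions over
#'   the four horizontal/axial flip states (undoing each flip on the
#'   output). Mirror-image studies are equally valid physics, so this
#'   reduces estimator variance at the cost of four forward passes; it
#'   pairs with the flip augmentation used in training.
#' @return `projection_set` of kind "mean_scatter" (non-negative).
#' @export
predict_scatter <- function(net, y, att, flip_average = TRUE) {
  stopifnot(inherits(net, "scatter_net"))
  d <- dim(y$values)
  if (!all(d[1:2] == net$spec$input_shape))
    stop("predict_scatter: projection size ", d[1], "x", d[2],
         " does not match the network input size ",
         paste(net$spec$input_shape, collapse = "x"))
  if (!all(dim(att$values) == d))
    stop("predict_scatter: attenuation projections do not match")
  fs <- scatter_scale_factor(net, y$values)
  flips <- if (flip_average)
    list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))
  else list(c(FALSE, FALSE))
  out <- array(0, d)
  for (v in seq_len(d[3])) {
    pv <- y$values[, , v] * fs
    av <- att$values[, , v] / net$att_divisor
    acc <- 0
    for (f in flips) {
      p1 <- pv; a1 <- av
      if (f[1]) { p1 <- p1[d[1]:1, ]; a1 <- a1[d[1]:1, ] }
      if (f[2]) { p1 <- p1[, d[2]:1]; a1 <- a1[, d[2]:1] }
      o <- scatter_net_fwd(net, array(p1, c(d[1:2], 1L)),
                           array(a1, c(d[1:2], 1L)))[, , 1]
      if (f[2]) o <- o[, d[2]:1]
      if (f[1]) o <- o[d[1]:1, ]
      acc <- acc + o / length(flips)
    }
    out[, , v] <- acc / fs
  }
  projection_set(out, y$geometry, "mean_scatter")
}
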