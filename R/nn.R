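# Minimal dense/conv network machinery shared by the scatter-estimation CNN
# and the residual dose network: parameter initialisation, ReLU, mean
# pooling / nearest-neighbour upsampling (both linear, with exact adjoint
# backward passes), channel concatenation and an Adam optimiser over nested
# parameter lists. Convolutions are Rcpp kernels (see src/nn_ops.cpp);
# everything is deterministic given the R RNG state.

# He-normal initialised conv2d parameter set, w: (kh, kw, cin, cout)
conv2d_params <- function(kh, kw, cin, cout, zero = FALSE) {
  n <- kh * kw * cin * cout
  if (zero) return(list(w = array(0, c(kh, kw, cin, cout)),
                        b = numeric(cout)))
  w <- array(stats::rnorm(n, sd = sqrt(2 / (kh * kw * cin))),
             c(kh, kw, cin, cout))
  # small positive bias keeps ReLU units alive at initialisation
  list(w = w, b = rep(0.01, cout))
}

conv3d_params <- function(kh, kw, kd, cin, cout) {
  n <- kh * kw * kd * cin * cout
  list(w = array(stats::rnorm(n, sd = sqrt(2 / (kh * kw * kd * cin))),
                 c(kh, kw, kd, cin, cout)),
       b = rep(0.01, cout))
}

conv2d_f <- function(x, p) conv2d_fwd_cpp(x, p$w, p$b, dim(x), dim(p$w))
conv2d_b <- function(x, p, gy) conv2d_bwd_cpp(x, p$w, gy, dim(x), dim(p$w))
conv3d_f <- function(x, p) conv3d_fwd_cpp(x, p$w, p$b, dim(x), dim(p$w))
conv3d_b <- function(x, p, gy) conv3d_bwd_cpp(x, p$w, gy, dim(x), dim(p$w))

relu_f <- function(x) { x[x < 0] <- 0; x }
relu_b <- function(y, g) { g[y <= 0] <- 0; g }

# 2x2 mean pooling (linear downsampler; exact adjoint backward)
pool2_f <- function(x) {
  d <- dim(x)
  (x[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
     x[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
     x[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
     x[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE]) / 4
}
pool2_b <- function(g, din) {
  gx <- array(0, din)
  gq <- g / 4
  gx[seq(1, din[1], 2), seq(1, din[2], 2), ] <- gq
  gx[seq(2, din[1], 2), seq(1, din[2], 2), ] <- gq
  gx[seq(1, din[1], 2), seq(2, din[2], 2), ] <- gq
  gx[seq(2, din[1], 2), seq(2, din[2], 2), ] <- gq
  gx
}

# nearest-neighbour 2x upsampling; backward sums 2x2 blocks
upsample2_f <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}
upsample2_b <- function(g) {
  d <- dim(g)
  (g[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
     g[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
     g[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
     g[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE])
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

# ---- Adam over nested lists of parameter arrays -----------------------------

nn_zeros_like <- function(p) {
  if (is.list(p)) lapply(p, nn_zeros_like)
  else { z <- p; z[] <- 0; z }
}

nn_axpy <- function(a, x, y) { # y + a * x over nested lists
  if (is.list(x)) Map(function(xi, yi) nn_axpy(a, xi, yi), x, y)
  else y + a * x
}

adam_init <- function(params) list(m = nn_zeros_like(params),
                                   v = nn_zeros_like(params), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

#' Network training recipe
#'
#' Optimiser settings shared by the two networks. The paper-scale presets
#' are [scatter_train_recipe_paper()] (Adam, lr 1e-4, 800 epochs) and
#' [dose_train_recipe_paper()] (Adam, lr 1e-3, 300 epochs, batch 32);
#' desk-scale runs use far fewer epochs.
#'
#' @param lr initial learning rate (> 0).
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param seed integer seed for shuffling (initialisation is seeded at
#'   network construction).
#' @param optimizer only "adam" is implemented.
#' @param loss only pixel-wise "mse" is implemented.
#' @export
train_config <- function(lr = 1e-4, epochs = 10L, batch_size = 8L, seed = 1L,
                         optimizer = "adam", loss = "mse") {
  stopifnot(lr >= 0, epochs >= 1, batch_size >= 1,
            optimizer == "adam", loss == "mse")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 optimizer = optimizer, loss = loss),
            class = "train_config")
}

#' @rdname train_config
#' @export
scatter_train_recipe_paper <- function() train_config(lr = 1e-4, epochs = 800L,
                                                      batch_size = 8L)

#' @rdname train_config
#' @export
dose_train_recipe_paper <- function() train_config(lr = 1e-3, epochs = 300L,
                                                   batch_size = 32L)
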