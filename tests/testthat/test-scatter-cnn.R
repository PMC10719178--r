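test_that("the scatter net preserves spatial size and is non-negative", {
  for (sz in list(c(32L, 24L), c(128L, 80L))) {
    net <- build_scatter_net(scatter_net_spec(sz, branch_channels = 4,
                                              trunk_channels = 8), seed = 3)
    pin <- with_seed(1, array(rnorm(prod(sz)), c(sz, 1L)))
    ain <- with_seed(2, array(rnorm(prod(sz)), c(sz, 1L)))
    out <- ybremdose:::scatter_net_fwd(net, pin, ain)
    expect_equal(dim(out)[1:2], sz)
    expect_true(all(out >= 0)) # terminal ReLU
  }
})

test_that("initialisation and inference are deterministic given the seed", {
  spec <- scatter_net_spec(c(16L, 12L), branch_channels = 4, trunk_channels = 8)
  a <- build_scatter_net(spec, seed = 7)
  b <- build_scatter_net(spec, seed = 7)
  expect_identical(a$params, b$params)
  c <- build_scatter_net(spec, seed = 8)
  expect_false(identical(a$params, c$params))
  pin <- with_seed(3, array(runif(16 * 12), c(16, 12, 1)))
  expect_identical(ybremdose:::scatter_net_fwd(a, pin, pin),
                   ybremdose:::scatter_net_fwd(b, pin, pin))
})

test_that("the network is shift-equivariant away from the borders", {
  sz <- c(40L, 30L)
  net <- build_scatter_net(scatter_net_spec(sz, branch_channels = 4,
                                            trunk_channels = 8), seed = 5)
  pin <- with_seed(4, array(runif(prod(sz)), c(sz, 1L)))
  ain <- with_seed(5, array(runif(prod(sz)), c(sz, 1L)))
  out <- ybremdose:::scatter_net_fwd(net, pin, ain)
  sh <- 5L
  shift <- function(x) { y <- array(0, dim(x)); y[(sh + 1):dim(x)[1], , ] <-
    x[1:(dim(x)[1] - sh), , , drop = FALSE]; y }
  out_sh <- ybremdose:::scatter_net_fwd(net, shift(pin), shift(ain))
  # interior bins (away from both borders by the receptive field + shift)
  rf <- 10L
  a <- out[(rf + 1):(sz[1] - rf - sh), (rf + 1):(sz[2] - rf), 1]
  b <- out_sh[(rf + sh + 1):(sz[1] - rf), (rf + 1):(sz[2] - rf), 1]
  expect_lt(max(abs(a - b)) / (max(abs(a)) + 1e-12), 1e-4)
})

test_that("training reduces the validation MSE on a learnable mapping", {
  # small synthetic study: the scatter is a smooth transform of the inputs
  sz <- c(16L, 12L)
  geom <- projection_geometry(n_views = 8, nu = sz[1], nv = sz[2],
                              pitch_mm = c(5, 5), radius_mm = 60)
  mk_study <- function(seed) {
    y <- with_seed(seed, array(rpois(prod(sz) * 8, 40), c(sz, 8L)))
    att <- array(rep(seq(0, 4, length.out = prod(sz)), 8), c(sz, 8L))
    sc <- 0.5 * y + 10
    list(y = projection_set(y, geom, "noisy_counts"),
         att = projection_set(att, geom, "attenuation_line_integral"),
         scatter = projection_set(sc, geom, "mean_scatter"))
  }
  net <- build_scatter_net(scatter_net_spec(sz, branch_channels = 4,
                                            trunk_channels = 8), seed = 2)
  net <- train_scatter_net(net, list(mk_study(1), mk_study(2)),
                           train_config(lr = 1e-3, epochs = 50,
                                        batch_size = 8, seed = 4),
                           val_studies = list(mk_study(3)))
  v <- net$history$val_mse
  expect_lt(v[length(v)], 0.25 * v[1])
  expect_true(net$trained)
})

test_that("zero learning rate leaves the parameters untouched", {
  sz <- c(12L, 10L)
  geom <- projection_geometry(n_views = 4, nu = sz[1], nv = sz[2],
                              pitch_mm = c(5, 5), radius_mm = 50)
  st <- list(y = projection_set(array(5, c(sz, 4L)), geom, "noisy_counts"),
             att = projection_set(array(1, c(sz, 4L)), geom,
                                  "attenuation_line_integral"),
             scatter = projection_set(array(2, c(sz, 4L)), geom,
                                      "mean_scatter"))
  net0 <- build_scatter_net(scatter_net_spec(sz, branch_channels = 4,
                                             trunk_channels = 8), seed = 2)
  net <- train_scatter_net(net0, list(st), train_config(lr = 0, epochs = 3),
                           val_studies = list(st))
  expect_identical(net$params, net0$params)
  expect_equal(diff(range(net$history$val_mse)), 0)
})

test_that("prediction rejects mismatched spatial sizes and inverts the scaling", {
  sz <- c(16L, 12L)
  geom <- projection_geometry(n_views = 4, nu = sz[1], nv = sz[2],
                              pitch_mm = c(5, 5), radius_mm = 60)
  net <- build_scatter_net(scatter_net_spec(sz, branch_channels = 4,
                                            trunk_channels = 8), seed = 2)
  y <- projection_set(array(7, c(sz, 4L)), geom, "noisy_counts")
  att <- projection_set(array(1, c(sz, 4L)), geom, "attenuation_line_integral")
  pred <- predict_scatter(net, y, att)
  expect_s3_class(pred, "projection_set")
  expect_true(all(pred$values >= 0) && all(is.finite(pred$values)))
  geom2 <- projection_geometry(n_views = 4, nu = 20, nv = 12,
                               pitch_mm = c(5, 5), radius_mm = 60)
  y2 <- projection_set(array(7, c(20, 12, 4)), geom2, "noisy_counts")
  att2 <- projection_set(array(1, c(20, 12, 4)), geom2,
                         "attenuation_line_integral")
  expect_error(predict_scatter(net, y2, att2), "does not match")
})

test_that("the paper-scale training recipe is preserved as a preset", {
  p <- scatter_train_recipe_paper()
  expect_equal(p$lr, 1e-4)
  expect_equal(p$epochs, 800L)
  d <- dose_train_recipe_paper()
  expect_equal(d$lr, 1e-3)
  expect_equal(d$batch_size, 32L)
  expect_equal(d$epochs, 300L)
})
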