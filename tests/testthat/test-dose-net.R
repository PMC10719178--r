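small_dose_spec <- function(pack = 5L)
  dose_net_spec(pack_depth = pack, extractor_kernel = 3,
                extractor_depths = c(3, 2, 2), extractor_channels = 4,
                unet_levels = 2, unet_base = 4)

# a tiny co-registered dose study on an (H, W, nz) grid: the network sees
# a blurred (reconstruction-like) activity, the ground truth comes from
# the sharp one, so there is a systematic residual to learn
tiny_dose_study <- function(seed, g = voxel_grid(c(16L, 16L, 8L), 5)) {
  with_seed(seed, {
    act <- array(0, g$shape)
    act[5:12, 5:12, 3:6] <- runif(8 * 8 * 4, 0.5, 1.5)
    act[7:9, 7:9, 4:5] <- 4
    den <- array(1, g$shape)
    blur <- ybremdose:::gaussian_smooth3(act, c(1.1, 1.1, 1.1))
    act <- voxel_volume(act, g, "activity_MBq")
    blur <- voxel_volume(blur, g, "activity_MBq")
    den <- voxel_volume(den, g, "density_g_per_cm3")
    k <- generate_dvk(g$voxel_size_mm, n_histories = 5e3, seed = seed + 1)
    dvk <- dvk_convolve(blur, k, den)
    gt <- mc_dose_rate(act, den, n_histories = 2e5, seed = seed + 2)
    list(activity = blur, density = den, dvk = dvk, gt = gt)
  })
}

test_that("the untrained residual network reproduces DVK dosimetry exactly", {
  st <- tiny_dose_study(21)
  net <- build_dose_net(small_dose_spec(), seed = 5)
  out <- predict_dose(net, st$activity, st$density, st$dvk)
  expect_equal(out$values, st$dvk$values, tolerance = 1e-14)
  expect_equal(out$provenance, "network")
  # zero activity: the DVK map is zero, so the output is zero
  zact <- voxel_volume(array(0, st$activity$grid$shape), st$activity$grid,
                       "activity_MBq")
  zdvk <- st$dvk; zdvk$values[] <- 0
  out0 <- predict_dose(net, zact, st$density, zdvk)
  expect_equal(max(abs(out0$values)), 0)
})

test_that("architecture constraints are enforced", {
  expect_error(dose_net_spec(pack_depth = 10), "odd")
  expect_error(dose_net_spec(pack_depth = 11, extractor_depths = c(5, 3, 3)),
               "collapse")
  # the figure and text variants are both constructible
  expect_s3_class(dose_net_spec(pack_depth = 11,
                                extractor_depths = c(5, 5, 3)),
                  "dose_net_spec")
  expect_s3_class(dose_net_spec(pack_depth = 9,
                                extractor_depths = c(5, 3, 3)),
                  "dose_net_spec")
})

test_that("in-plane size is preserved and init is seed-deterministic", {
  for (hw in list(c(16L, 16L), c(32L, 32L))) {
    g <- voxel_grid(c(hw, 8L), 5)
    net <- build_dose_net(small_dose_spec(), seed = 9)
    ap <- with_seed(1, array(runif(prod(g$shape[1:2]) * 5), c(g$shape[1:2], 5)))
    res <- ybremdose:::dose_net_fwd(net, ap, ap)
    expect_equal(dim(res)[1:2], hw)
  }
  a <- build_dose_net(small_dose_spec(), seed = 4)
  b <- build_dose_net(small_dose_spec(), seed = 4)
  expect_identical(a$params, b$params)
})

test_that("training beats the DVK baseline; zero learning rate keeps it", {
  s1 <- tiny_dose_study(31)
  s2 <- tiny_dose_study(32)
  net <- build_dose_net(small_dose_spec(), seed = 2)
  tr <- train_dose_net(net, list(s1), train_config(lr = 1e-3, epochs = 8,
                                                   batch_size = 4, seed = 3),
                       val_studies = list(s2))
  v <- tr$history$val_mse
  # epoch 0 is exactly the DVK-baseline validation MSE (zero residual)
  expect_lt(min(v), v[1])
  expect_lt(v[length(v)], v[1])
  frozen <- train_dose_net(net, list(s1), train_config(lr = 0, epochs = 2),
                           val_studies = list(s2))
  out <- predict_dose(frozen, s1$activity, s1$density, s1$dvk)
  expect_equal(out$values, s1$dvk$values, tolerance = 1e-14)
})

test_that("ground-truth labels must be MC maps on a co-registered grid", {
  s1 <- tiny_dose_study(41)
  bad <- s1; bad$gt <- bad$dvk # DVK provenance is not a valid label
  net <- build_dose_net(small_dose_spec(), seed = 2)
  expect_error(train_dose_net(net, list(bad)), "MC")
  g2 <- voxel_grid(c(16L, 16L, 8L), 4)
  s1b <- s1
  s1b$gt$grid <- g2
  expect_error(train_dose_net(net, list(s1b)), "co-registered")
})

test_that("activity scaling round-trips to machine precision", {
  st <- tiny_dose_study(61)
  net <- build_dose_net(small_dose_spec(), seed = 1)
  s <- ybremdose:::activity_scale(net, st$activity)
  # scaled voxels have unit mean regardless of grid size or total activity
  expect_equal(mean(st$activity$values * s), net$scaled_mean,
               tolerance = 1e-12)
  x <- with_seed(2, runif(100) * 3)
  expect_equal((x * s) / s, x, tolerance = 1e-12)
})

test_that("the single-stage variant guards against scatter-corrected input", {
  st <- tiny_dose_study(51)
  net <- build_dose_net(small_dose_spec(), seed = 5, variant = "single_stage")
  act_sc <- st$activity
  attr(act_sc, "scatter_corrected") <- TRUE
  expect_error(predict_dose(net, act_sc, st$density, st$dvk), "no-SC")
  # a no-SC reconstruction passes, and the untrained variant returns its DVK
  act_no <- st$activity
  attr(act_no, "scatter_corrected") <- FALSE
  out <- predict_dose(net, act_no, st$density, st$dvk)
  expect_equal(out$values, st$dvk$values, tolerance = 1e-14)
  expect_error(predict_dose(net, act_no, NULL, st$dvk), "density")
})

test_that("inference is shift-equivariant in-plane away from borders", {
  n <- 48L
  net <- build_dose_net(small_dose_spec(), seed = 8)
  # give the residual head non-zero weights so the test is non-trivial
  net$params$head <- with_seed(9, ybremdose:::conv2d_params(3, 3, 4, 1))
  ap <- with_seed(3, array(runif(n * n * 5), c(n, n, 5)))
  dp <- with_seed(4, array(runif(n * n * 5) + 0.5, c(n, n, 5)))
  res <- ybremdose:::dose_net_fwd(net, ap, dp)
  sh <- 4L # a multiple of the U-Net pooling factor
  shift <- function(x) { y <- array(0, dim(x))
    y[(sh + 1):n, , ] <- x[1:(n - sh), , , drop = FALSE]; y }
  res_sh <- ybremdose:::dose_net_fwd(net, shift(ap), shift(dp))
  rf <- 16L # half-width of the total receptive field
  a <- res[(rf + 1):(n - rf - sh), (rf + 1):(n - rf), 1]
  b <- res_sh[(rf + sh + 1):(n - rf), (rf + 1):(n - rf), 1]
  expect_lt(max(abs(a - b)) / (max(abs(a)) + 1e-12), 1e-4)
})
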