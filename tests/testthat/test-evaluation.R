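test_that("NMAE implements the printed difference-of-means form", {
  expect_equal(nmae(c(1, 2, 3), c(1, 2, 3)), 0)
  # means equal although voxels differ: the printed formula gives 0
  expect_equal(nmae(c(2, 2), c(1, 3)), 0)
  expect_equal(nmae(c(1, 1, 1, 1), c(2, 2, 2, 2)), 100)
  # the voxelwise companion does see the discrepancy
  expect_equal(voxelwise_mae(c(2, 2), c(1, 3)), 50)
  expect_error(nmae(c(0, 0), c(1, 1)), "positive")
})

test_that("NRMSE implements RMSE over the GT root-mean-square", {
  expect_equal(nrmse(c(1, 2), c(1, 2)), 0)
  # hand computation: RMSE = 1, RMS of (1,2) = sqrt(2.5)
  expect_equal(nrmse(c(1, 2), c(2, 1)), 100 / sqrt(2.5), tolerance = 1e-12)
  expect_equal(round(nrmse(c(1, 2), c(2, 1)), 2), 63.25)
  # the zero estimate scores exactly 100% for any non-zero truth
  x <- with_seed(1, runif(50))
  expect_equal(nrmse(x, rep(0, 50)), 100, tolerance = 1e-12)
  expect_error(nrmse(c(0, 0), c(1, 1)), "zero")
})

test_that("error metrics scale linearly and ignore voxel order", {
  x <- with_seed(2, runif(64) + 1)
  e <- with_seed(3, rnorm(64))
  expect_equal(nrmse(x, x + 2 * e), 2 * nrmse(x, x + e), tolerance = 1e-9)
  p <- with_seed(4, sample.int(64))
  expect_equal(nrmse(x[p], (x + e)[p]), nrmse(x, x + e), tolerance = 1e-12)
  expect_equal(nmae(x[p], (x + e)[p]), nmae(x, x + e), tolerance = 1e-12)
})

test_that("DRVH matches the sort-based oracle and its invariants", {
  # linear ramp: D10 = 91, D90 = 11
  ramp <- array(1:100, c(100, 1, 1))
  h <- drvh(ramp)
  expect_equal(d_at(h, 0.1), 91)
  expect_equal(d_at(h, 0.9), 11)
  # uniform region: D10 = D90 = value
  u <- drvh(array(7.5, c(20, 1, 1)))
  expect_equal(d_at(u, 0.1), 7.5)
  expect_equal(d_at(u, 0.9), 7.5)
  # invariants + round trip against an exhaustive sorting oracle
  for (i in 1:50) {
    v <- with_seed(i, array(rexp(60), c(60, 1, 1)))
    h <- drvh(v)
    expect_equal(h$fractions[1], 1)
    expect_equal(h$fractions[length(h$fractions)], 0)
    expect_true(all(diff(h$fractions) <= 0))
    sv <- sort(as.numeric(v), decreasing = TRUE)
    for (f in c(0.1, 0.25, 0.5, 0.9))
      expect_equal(d_at(h, f), sv[ceiling(f * 60)])
  }
})

test_that("background VOIs are congruent to the lesion and placed in uniform liver", {
  g <- voxel_grid(c(32L, 32L, 16L), 5)
  liver <- array(FALSE, g$shape); liver[4:29, 4:29, 3:14] <- TRUE
  lesion <- array(FALSE, g$shape); lesion[8:11, 8:11, 7:9] <- TRUE
  base <- array(2, g$shape)
  map <- base; map[lesion] <- 10 # 5x background
  mv <- voxel_volume(map, g, "dose_rate_nGy_per_s")
  res <- lesion_to_background(mv, lesion, liver, list(lesion))
  expect_equal(sum(res$background_mask), sum(lesion))
  expect_false(any(res$background_mask & lesion))
  expect_true(all(liver[res$background_mask]))
  expect_lt(abs(res$ratio - 5) / 5, 0.01)
  # uniform map: ratio 1 regardless of placement
  uni <- voxel_volume(base, g, "dose_rate_nGy_per_s")
  expect_equal(lesion_to_background(uni, lesion, liver)$ratio, 1)
  # infeasible placement is rejected with diagnostics
  tiny_liver <- lesion # no room for a disjoint copy
  expect_error(lesion_to_background(mv, lesion, tiny_liver), "feasible")
})

test_that("metrics reports aggregate per-VOI rows", {
  g <- voxel_grid(c(16L, 16L, 8L), 5)
  liver <- array(FALSE, g$shape); liver[3:14, 3:14, 2:7] <- TRUE
  l1 <- array(FALSE, g$shape); l1[5:7, 5:7, 3:5] <- TRUE
  vois <- voi_set(g, lesions = list(l1), liver = liver)
  gt <- voxel_volume(array(4, g$shape), g, "dose_rate_nGy_per_s")
  est <- voxel_volume(array(5, g$shape), g, "dose_rate_nGy_per_s")
  rep <- metrics_report(gt, est, vois)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$nmae_pct, c(25, 25))
  expect_equal(rep$n_p[1], sum(l1))
  s <- metrics_summary(rep)
  expect_equal(s$nmae_mean, 25)
  expect_equal(s$n_vois, 2)
  p <- plot_drvh(list(a = drvh(gt$values), b = drvh(est$values)))
  expect_s3_class(p, "ggplot")
})
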