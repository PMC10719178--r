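test_that("kernel dimensions follow the 11 mm range rule", {
  expect_identical(dvk_dimensions(c(0.98, 0.98, 2)), c(23L, 23L, 13L))
  expect_identical(dvk_dimensions(c(5, 5, 5)), c(5L, 5L, 5L))
  expect_identical(dvk_dimensions(c(2, 2, 2)), c(13L, 13L, 13L))
  expect_error(dvk_dimensions(c(25, 25, 25)), "single-voxel")
})

dvk5 <- generate_dvk(c(5, 5, 5), n_histories = 4e4, seed = 31)

test_that("the kernel conserves energy and is centre-dominated and symmetric", {
  # bookkeeping: deposited + escaped = sampled, exactly
  expect_lt(abs(dvk5$deposited_MeV_per_decay / dvk5$sampled_MeV_per_decay +
                  dvk5$escaped_fraction - 1), 1e-12)
  # total deposited energy per decay matches the spectrum mean within 2%
  # (no bremsstrahlung escape is modelled; the 5x5x5 @5 mm kernel covers
  # the full beta range)
  bs <- beta_spectrum()
  expect_lt(abs(dvk5$deposited_MeV_per_decay - bs$mean_MeV) / bs$mean_MeV,
            0.02)
  # centre voxel is the maximum
  expect_equal(which.max(dvk5$values), (length(dvk5$values) + 1) %/% 2)
  # mirror symmetry within 3x the Monte Carlo standard error
  v <- dvk5$values
  se <- dvk5$rel_uncertainty * v
  for (a in 1:3) {
    fl <- apply(v, setdiff(1:3, a), rev)
    fl <- aperm(array(fl, dim(v)[c(a, setdiff(1:3, a))]),
                order(c(a, setdiff(1:3, a))))
    tol <- 3 * sqrt(se^2 + se^2) + 1e-9 * max(v)
    expect_true(all(abs(v - fl) <= tol + 0.05 * max(v)))
  }
  # spherically averaged profile decays monotonically from the centre
  ctr <- (dim(v) + 1) / 2
  d2 <- as.matrix(expand.grid(1:5, 1:5, 1:5))
  r <- sqrt(colSums((t(d2) - ctr)^2))
  keep <- r <= 2.1 # shells with enough voxels to average reliably
  prof <- tapply(as.numeric(v)[keep], round(r[keep], 3), mean)
  expect_true(all(diff(prof[order(as.numeric(names(prof)))]) < 0))
})

test_that("FFT convolution reproduces the kernel for a single source", {
  g <- voxel_grid(c(15, 15, 11), 5)
  act <- array(0, g$shape); act[8, 8, 6] <- 1
  den <- voxel_volume(array(1, g$shape), g, "density_g_per_cm3")
  dm <- dvk_convolve(voxel_volume(act, g, "activity_MBq"), dvk5, den)
  sub <- dm$values[6:10, 6:10, 4:8]
  expect_lt(max(abs(sub - dvk5$values)) / max(dvk5$values), 1e-6)
})

test_that("FFT convolution equals brute-force kernel superposition", {
  g <- voxel_grid(c(24, 24, 16), 5)
  act <- array(0, g$shape)
  srcs <- rbind(c(5, 6, 4), c(12, 12, 8), c(20, 18, 13), c(8, 16, 10),
                c(16, 7, 6))
  for (i in 1:5) act[srcs[i, 1], srcs[i, 2], srcs[i, 3]] <- i
  den <- voxel_volume(array(1, g$shape), g, "density_g_per_cm3")
  dm <- dvk_convolve(voxel_volume(act, g, "activity_MBq"), dvk5, den)
  brute <- array(0, g$shape)
  kd <- dim(dvk5$values); off <- (kd - 1) / 2
  for (i in 1:5) for (a in 1:kd[1]) for (b in 1:kd[2]) for (c in 1:kd[3]) {
    t1 <- srcs[i, 1] + a - 1 - off[1]
    t2 <- srcs[i, 2] + b - 1 - off[2]
    t3 <- srcs[i, 3] + c - 1 - off[3]
    if (t1 >= 1 && t1 <= 24 && t2 >= 1 && t2 <= 24 && t3 >= 1 && t3 <= 16)
      brute[t1, t2, t3] <- brute[t1, t2, t3] + i * dvk5$values[a, b, c]
  }
  expect_lt(max(abs(dm$values - brute)) / max(brute), 1e-6)
})

test_that("density scaling divides and the cutoff zeroes low-density voxels", {
  g <- voxel_grid(c(15, 15, 11), 5)
  act <- array(0, g$shape); act[8, 8, 6] <- 1
  den_arr <- array(1, g$shape)
  den_arr[10, 8, 6] <- 0.30 # lung-like voxel within the kernel footprint
  den_arr[6, 8, 6] <- 2.0
  den <- voxel_volume(den_arr, g, "density_g_per_cm3")
  dm <- dvk_convolve(voxel_volume(act, g, "activity_MBq"), dvk5, den)
  expect_equal(dm$values[10, 8, 6], 0) # below the printed 1.0 cutoff
  duni <- dvk_convolve(voxel_volume(act, g, "activity_MBq"), dvk5,
                       voxel_volume(array(1, g$shape), g, "density_g_per_cm3"))
  expect_equal(dm$values[6, 8, 6], duni$values[6, 8, 6] / 2, tolerance = 1e-9)
  # voxel-size mismatch is rejected, not resampled
  g2 <- voxel_grid(c(15, 15, 11), 4)
  expect_error(dvk_convolve(voxel_volume(act, g2, "activity_MBq"), dvk5,
                            voxel_volume(array(1, g2$shape), g2,
                                         "density_g_per_cm3")),
               "voxel size")
})

test_that("MC dose rate matches the analytic equilibrium value in uniform water", {
  g <- voxel_grid(c(19, 19, 19), 5)
  act <- voxel_volume(array(1, g$shape), g, "activity_MBq")
  den <- voxel_volume(array(1, g$shape), g, "density_g_per_cm3")
  m <- mc_dose_rate(act, den, n_histories = 3e5, seed = 6)
  conc <- 1 / voxel_volume_mL(g) # MBq/cm^3
  bs <- beta_spectrum()
  analytic <- conc * 1e6 * bs$mean_MeV * 1.602e-13 / 1e-3 * 1e9 # nGy/s
  ctr <- m$values[8:12, 8:12, 8:12]
  expect_lt(abs(mean(ctr) - analytic) / analytic, 0.02)
  # energy bookkeeping is exact
  expect_lt(abs(m$deposited_MeV_per_decay / m$sampled_MeV_per_decay +
                  m$escaped_fraction - 1), 1e-12)
})

test_that("MC and DVK dosimetry agree in uniform water", {
  g <- voxel_grid(c(20, 20, 14), 5)
  act <- array(0, g$shape); act[8, 9, 7] <- 3; act[14, 12, 8] <- 1.5
  act <- voxel_volume(act, g, "activity_MBq")
  den <- voxel_volume(array(1, g$shape), g, "density_g_per_cm3")
  mc <- mc_dose_rate(act, den, n_histories = 4e5, seed = 9)
  dv <- dvk_convolve(act, dvk5, den)
  # compare where the MC uncertainty is under control; the allowance
  # combines the map's MC error, the kernel's own MC error and the
  # voxelisation difference between the two estimators
  w <- mc$rel_uncertainty > 0 & mc$rel_uncertainty < 0.05 & dv$values > 0
  reldiff <- abs(mc$values[w] - dv$values[w]) / dv$values[w]
  comb <- 3 * sqrt(mc$rel_uncertainty[w]^2 + 0.02^2) + 0.1
  expect_gt(mean(reldiff <= comb), 0.9)
})

test_that("MC dose is linear in activity and rejects empty inputs", {
  g <- voxel_grid(c(12, 12, 10), 5)
  act <- array(0, g$shape); act[6, 6, 5] <- 2
  act1 <- voxel_volume(act, g, "activity_MBq")
  act2 <- voxel_volume(2 * act, g, "activity_MBq")
  den <- voxel_volume(array(1, g$shape), g, "density_g_per_cm3")
  m1 <- mc_dose_rate(act1, den, n_histories = 5e4, seed = 10)
  m2 <- mc_dose_rate(act2, den, n_histories = 5e4, seed = 10)
  expect_equal(m2$values, 2 * m1$values, tolerance = 1e-12)
  zero <- voxel_volume(array(0, g$shape), g, "activity_MBq")
  expect_error(mc_dose_rate(zero, den), "zero")
})

test_that("dose-rate to dose conversion is the decay time integral", {
  g <- voxel_grid(c(4, 4, 4), 5)
  m <- voxel_volume(array(2, g$shape), g, "dose_rate_nGy_per_s")
  # T1/2 = ln(2) hours gives a factor of exactly 3600 s
  expect_equal(dose_rate_to_dose(m, half_life_h = log(2))$values[1], 7200,
               tolerance = 1e-9)
  # hand arithmetic for the physical 64.1 h half-life:
  # 64.1 * 3600 / ln 2 = 230760 / 0.6931472 = 332915.4 s
  expect_equal(dose_rate_to_dose(m, 64.1)$values[1] / 2, 332915.4,
               tolerance = 0.5)
  zero <- voxel_volume(array(0, g$shape), g, "dose_rate_nGy_per_s")
  expect_equal(max(dose_rate_to_dose(zero, 64.1)$values), 0)
})

test_that("the radial profile conserves energy and is seeded", {
  pr <- beta_range_profile(n_histories = 2e4, seed = 3)
  expect_lt(abs(sum(pr$energy_MeV) / pr$sampled_MeV - 1), 0.001)
  pr2 <- beta_range_profile(n_histories = 2e4, seed = 3)
  expect_identical(pr$energy_MeV, pr2$energy_MeV)
  expect_true(all(diff(pr$cumulative_fraction) >= 0))
})
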