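test_that("lesion masks match requested volumes to within one voxel volume", {
  cfg <- phantom_config(seed = 4, grid = voxel_grid(c(48, 48, 32), 5),
                        lesion_volumes_mL = c(29.6, 27.4, 21.0, 5.7),
                        liver_volume_mL = 1500)
  ph <- make_virtual_patient(cfg)
  vv <- voxel_volume_mL(ph$activity$grid)
  got <- sapply(ph$vois$lesions, mask_volume_mL, grid = ph$activity$grid)
  expect_true(all(abs(got - c(29.6, 27.4, 21.0, 5.7)) <= vv + 1e-9))
  # mask algebra
  any_les <- Reduce(`|`, ph$vois$lesions)
  expect_false(any(ph$vois$healthy_liver & any_les))
  expect_equal(ph$vois$healthy_liver | any_les, ph$vois$liver)
  # activity budget: sum equals the configured total within 0.5%
  expect_lt(abs(sum(ph$activity$values) - 2000) / 2000, 0.005)
  # activity is zero outside the liver
  expect_equal(sum(ph$activity$values[!ph$vois$liver]), 0)
})

test_that("phantom generation is bit-identical for the same seed", {
  cfg <- phantom_config(seed = 9, grid = voxel_grid(c(32, 32, 20), 6),
                        lesion_volumes_mL = c(25), liver_volume_mL = 1200)
  a <- make_virtual_patient(cfg)
  b <- make_virtual_patient(cfg)
  expect_identical(a$activity$values, b$activity$values)
  expect_identical(a$density$values, b$density$values)
  expect_identical(a$vois$lesions, b$vois$lesions)
})

test_that("degenerate texture with unit uptake gives equal lesion and liver concentration", {
  cfg <- phantom_config(seed = 2, grid = voxel_grid(c(32, 32, 20), 6),
                        lesion_volumes_mL = c(40, 12),
                        lesion_uptake_ratios = 1, texture_sigma = 0)
  ph <- make_virtual_patient(cfg)
  m_hl <- mean(ph$activity$values[ph$vois$healthy_liver])
  for (les in ph$vois$lesions)
    expect_equal(mean(ph$activity$values[les]), m_hl, tolerance = 1e-12)
})

test_that("impossible lesion requests are rejected with an explanation", {
  cfg <- phantom_config(seed = 1, grid = voxel_grid(c(32, 32, 20), 6),
                        lesion_volumes_mL = c(1600), liver_volume_mL = 1500)
  expect_error(make_virtual_patient(cfg), "exceed")
})

test_that("torso phantom matches its printed activity budget", {
  ph <- make_torso_phantom(scale = 1, seed = 3,
                           grid = voxel_grid(c(48, 48, 32), 5))
  tot <- sum(ph$activity$values)
  expect_lt(abs(tot - 2000) / 2000, 0.02) # 2.0 GBq within 2%
  # insert-to-background concentration ratio: 6.5 / 1.3 = 5
  ph2 <- make_torso_phantom(scale = 1, seed = 3,
                            grid = voxel_grid(c(48, 48, 32), 5),
                            insert_conc_MBq_mL = c(6.5, 6.5, 6.5))
  vv <- voxel_volume_mL(ph2$activity$grid)
  conc1 <- mean(ph2$activity$values[ph2$vois$lesions[[1]]]) / vv
  concb <- mean(ph2$activity$values[ph2$vois$healthy_liver]) / vv
  expect_equal(conc1 / concb, 5, tolerance = 1e-9)
  # compartment volumes: liver 1200 mL background + 29/16/8 mL inserts
  expect_equal(mask_volume_mL(ph$vois$healthy_liver, ph$activity$grid), 1200,
               tolerance = vv * 5)
  expect_equal(sapply(ph$vois$lesions, mask_volume_mL, grid = ph$activity$grid),
               c(29, 16, 8), tolerance = vv + 1e-9)
  # zero scaling empties the activity but not the density
  ph0 <- make_torso_phantom(scale = 0, seed = 3,
                            grid = voxel_grid(c(48, 48, 32), 5))
  expect_equal(sum(ph0$activity$values), 0)
  expect_identical(ph0$density$values, ph$density$values)
})

test_that("CT-to-density calibration hits its anchors and stays monotone", {
  expect_equal(ct_to_density(0), 1.000, tolerance = 1e-12)
  expect_equal(ct_to_density(-1000), 0.0012, tolerance = 1e-12)
  # hand evaluation of the two-segment curve at +1000 HU:
  # 1.0 + 1000 * 0.60/1000 = 1.60
  expect_equal(ct_to_density(1000), 1.60, tolerance = 1e-12)
  hu <- seq(-1500, 2000, by = 10)
  d <- ct_to_density(hu)
  expect_true(all(diff(d) >= 0))
  expect_true(all(d >= 0))
})

test_that("density-to-attenuation uses the water table and is linear in density", {
  g <- voxel_grid(c(4, 4, 4), 2)
  water <- voxel_volume(array(1, g$shape), g, "density_g_per_cm3")
  mu <- density_to_attenuation(water, 150)
  # independent log-log interpolation of the embedded table: 150 keV is a
  # table node, 0.1505 cm^-1
  expect_equal(mu$values[1], 0.1505, tolerance = 1e-9)
  zero <- voxel_volume(array(0, g$shape), g, "density_g_per_cm3")
  expect_equal(max(abs(density_to_attenuation(zero, 150)$values)), 0)
  dbl <- voxel_volume(array(2, g$shape), g, "density_g_per_cm3")
  expect_equal(density_to_attenuation(dbl, 150)$values, 2 * mu$values)
  # interpolated (non-node) energy, checked against direct interpolation
  mu100 <- water_mass_attenuation(120, "total")
  expect_equal(mu100,
               exp(approx(log(c(100, 150)), log(c(0.1707, 0.1505)),
                          xout = log(120))$y),
               tolerance = 1e-12)
  expect_error(density_to_attenuation(water, 20), "range")
  expect_error(density_to_attenuation(water, 5000), "range")
})
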