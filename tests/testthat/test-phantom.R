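# Synthetic phantom generator: geometry, HU profiles, masks and ground truth.

test_that("an insert-free phantom is pure sub-floor background", {
  ph <- generate_phantom(phantom_spec(seed = 3), grid_shape = c(20, 20, 8))
  expect_length(ph$masks, 0)
  expect_lt(max(ph$grid$data), 130)
  expect_true(all(ph$grid$data >= -1024))
})

test_that("a uniform insert forces the mean density and exact voxel volume", {
  ins <- calc_insert("ICA_left", center_mm = c(14, 14, 24), radii_mm = 3,
                     hu_profile = hu_uniform(300))
  ph <- generate_phantom(phantom_spec(list(ins), seed = 11))
  m <- threshold_profile(ph$grid, ph$masks$ICA_left)
  supra <- ph$grid$data[ph$masks$ICA_left & ph$grid$data >= 130]
  expect_true(all(supra == 300L))
  expect_identical(m$profile$mean_hu[1], 300)
  expect_identical(m$profile$volume_mm3[1],
                   m$profile$voxel_count[1] * prod(c(0.6, 0.6, 3.0)))
  expect_identical(as.character(m$density_category), "300-400")
})

test_that("a graded insert averages strictly between rim and core, matching
          a brute-force voxel average", {
  ins <- calc_insert("basilar", center_mm = c(14, 14, 24), radii_mm = 4,
                     hu_profile = hu_graded(800, 200))
  ph <- generate_phantom(phantom_spec(list(ins), seed = 21))
  m <- threshold_profile(ph$grid, ph$masks$basilar)
  # independent average straight off the emitted grid
  vox <- ph$grid$data[ph$masks$basilar & ph$grid$data >= 130]
  expect_equal(m$profile$mean_hu[1], sum(as.numeric(vox)) / length(vox))
  expect_gt(m$profile$mean_hu[1], 200)
  expect_lt(m$profile$mean_hu[1], 800)
})

test_that("invalid geometry is rejected with the offending insert named", {
  ok <- calc_insert("ICA_left", center_mm = c(14, 14, 24), radii_mm = 3)
  out <- calc_insert("basilar", center_mm = c(1, 14, 24), radii_mm = 3)
  expect_error(generate_phantom(phantom_spec(list(ok, out)), c(48, 48, 16)),
               "insert 2 \\(basilar\\)")
  expect_error(generate_phantom(phantom_spec(list(ok)), c(48, 48, 16),
                                spacing = c(0.6, -1, 3)),
               "strictly positive")
  expect_error(calc_insert("ICA_left", c(5, 5, 5), radii_mm = 2,
                           hu_profile = hu_graded(200, 800)),
               "core_hu >= rim_hu")
})

test_that("truth table: sub-floor inserts have zero volume and no category", {
  ins <- calc_insert("ICA_right", center_mm = c(14, 14, 24), radii_mm = 3,
                     hu_profile = hu_uniform(100))
  ph <- generate_phantom(phantom_spec(list(ins), seed = 5))
  tt <- truth_table(ph)
  expect_identical(tt$n_voxels, 0L)
  expect_identical(tt$realized_volume_mm3, 0)
  expect_true(is.na(tt$realized_mean_hu))
  expect_true(is.na(tt$realized_category))
})

test_that("truth table and quantify module agree bit-for-bit on seeded
          phantoms", {
  for (seed in 101:110) expect_phantom_agreement(random_phantom(seed))
})

test_that("halving the slice thickness moves realized volume toward the
          analytic insert volume", {
  ins <- calc_insert("ICA_left", center_mm = c(14.3, 13.7, 23.1),
                     radii_mm = 4, hu_profile = hu_uniform(400))
  coarse <- generate_phantom(phantom_spec(list(ins), seed = 8),
                             grid_shape = c(48, 48, 16),
                             spacing = c(0.6, 0.6, 3.0))
  fine <- generate_phantom(phantom_spec(list(ins), seed = 8),
                           grid_shape = c(48, 48, 32),
                           spacing = c(0.6, 0.6, 1.5))
  v_true <- ins$true_volume_mm3
  expect_equal(v_true, 4 / 3 * pi * 4^3)
  err_coarse <- abs(truth_table(coarse)$realized_volume_mm3 - v_true)
  err_fine <- abs(truth_table(fine)$realized_volume_mm3 - v_true)
  expect_lt(err_fine, err_coarse)
})

test_that("a fixed seed reproduces the phantom bit-identically", {
  p1 <- random_phantom(77)
  p2 <- random_phantom(77)
  expect_identical(p1$grid$data, p2$grid$data)
  expect_identical(p1$masks, p2$masks)
})

test_that("phantom round-trips through NIfTI with spacing preserved", {
  ph <- random_phantom(55)
  d <- withr::local_tempdir()
  paths <- write_phantom(ph, d)
  back <- read_volume_nifti(paths[["grid"]])
  expect_identical(back$data, ph$grid$data)
  expect_equal(back$spacing, ph$grid$spacing, tolerance = 1e-6)
})
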