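# Measurement core: detection, density, volume, ladder profiles, the 7-bin
# categorization and participant aggregation.

test_that("detection respects the inclusive floor and the mask", {
  lg <- line_grid(c(40, 129, 130, 131, 500))
  expect_identical(detect_voxels(lg$grid, lg$mask, 130), c(3L, 4L, 5L))
  lg2 <- line_grid(rep(40, 25))
  expect_length(detect_voxels(lg2$grid, lg2$mask, 130), 0)
  half <- lg$mask; half[1:3] <- FALSE
  expect_identical(detect_voxels(lg$grid, half, 130), c(4L, 5L))
  expect_error(detect_voxels(lg$grid, half[1:2, , , drop = FALSE], 130),
               "dimensions")
})

test_that("detection equals an exhaustive voxel scan on a random grid", {
  set.seed(42)
  g <- voxel_grid(array(sample(0:1200, 18 * 9 * 4, replace = TRUE),
                        dim = c(18, 9, 4)))
  mask <- array(sample(c(TRUE, FALSE), 18 * 9 * 4, replace = TRUE),
                dim = c(18, 9, 4))
  expect_identical(detect_voxels(g, mask, 300), brute_force_detect(g, mask, 300))
})

test_that("mean density is the plain HU average, absent when nothing is
          detected", {
  lg <- line_grid(c(150, 200, 250))
  expect_identical(mean_density(lg$grid, 1:3), 200)
  expect_identical(mean_density(lg$grid, 2L), 200)
  expect_identical(mean_density(lg$grid, integer(0)), NA_real_)
  set.seed(7)
  hu <- sample(130:2000, 10000, replace = TRUE)
  lg2 <- line_grid(hu)
  idx <- detect_voxels(lg2$grid, lg2$mask, 130)
  expect_equal(mean_density(lg2$grid, idx), sum(as.numeric(hu)) / 10000,
               tolerance = 1e-15)
})

test_that("volume is voxel count times voxel volume", {
  expect_equal(calc_volume(1:10, c(0.6, 0.6, 3.0)), 10.8)
  expect_identical(calc_volume(integer(0), c(0.6, 0.6, 3.0)), 0)
  expect_error(calc_volume(1:3, c(0.6, 0, 3)), "strictly positive")
})

test_that("a uniform-value artery yields identical ladder records up to its
          value and empty ones beyond", {
  m <- measure_hu(c(rep(40, 5), rep(300, 7)))
  prof <- m$profile
  same <- prof$threshold <= 300
  expect_true(all(prof$voxel_count[same] == 7L))
  expect_true(all(prof$mean_hu[same] == 300))
  expect_true(all(prof$voxel_count[!same] == 0L))
  expect_true(all(is.na(prof$mean_hu[!same])))
  expect_identical(m$max_hu, 300)
})

test_that("ladder profiles are monotone on seeded phantoms: counts and
          volumes non-increasing, mean density non-decreasing", {
  for (seed in 201:215) {
    ph <- random_phantom(seed)
    for (m in quantify_phantom(ph)) {
      prof <- m$profile
      expect_true(all(diff(prof$voxel_count) <= 0))
      expect_true(all(diff(prof$volume_mm3) <= 0))
      mh <- prof$mean_hu[!is.na(prof$mean_hu)]
      if (length(mh) > 1) expect_true(all(diff(mh) >= -1e-12))
      pres <- !is.na(prof$mean_hu)
      expect_true(all(prof$mean_hu[pres] >= prof$threshold[pres]))
    }
  }
})

test_that("adding a constant to every supra-floor voxel shifts mean density
          by exactly that constant", {
  ins <- calc_insert("ICA_left", center_mm = c(14, 14, 24), radii_mm = 4,
                     hu_profile = hu_graded(900, 150))
  ph <- generate_phantom(phantom_spec(list(ins), seed = 13))
  a <- "ICA_left"
  m0 <- threshold_profile(ph$grid, ph$masks[[a]])
  shifted <- ph$grid$data
  sel <- ph$masks[[a]] & shifted >= 130
  shifted[sel] <- shifted[sel] + 57L
  m1 <- threshold_profile(voxel_grid(shifted, ph$grid$spacing), ph$masks[[a]])
  expect_identical(m1$profile$voxel_count[1], m0$profile$voxel_count[1])
  expect_equal(m1$profile$mean_hu[1], m0$profile$mean_hu[1] + 57)
})

test_that("density categories follow the documented bin conventions", {
  expect_identical(as.character(assign_density_category(450)), "400-600")
  expect_identical(as.character(assign_density_category(200)), "200-300")
  expect_identical(as.character(assign_density_category(130)), "130-200")
  expect_identical(as.character(assign_density_category(1000)), "800-1000")
  expect_identical(as.character(assign_density_category(1000.5)), ">1000")
  expect_true(is.na(assign_density_category(NA)))
  expect_error(assign_density_category(129), "floor")
})

test_that("vectorized categorization matches an independent bin-lookup sweep", {
  breaks <- list(`130-200` = c(130, 200), `200-300` = c(200, 300),
                 `300-400` = c(300, 400), `400-600` = c(400, 600),
                 `600-800` = c(600, 800), `800-1000` = c(800, 1000.5),
                 `>1000` = c(1000.5, Inf))   # top bin closed at 1000
  lookup <- function(v) {
    for (nm in names(breaks))
      if (v >= breaks[[nm]][1] && v < breaks[[nm]][2]) return(nm)
  }
  sweep <- seq(130, 1500, by = 0.5)
  expect_identical(as.character(assign_density_category(sweep)),
                   vapply(sweep, lookup, character(1)))
})

test_that("participant aggregation averages per artery, not per voxel", {
  m1 <- measure_hu(rep(200, 30), "ICA_left")    # large artery, mean 200
  m2 <- measure_hu(rep(300, 3), "ICA_right")    # small artery, mean 300
  agg <- aggregate_participant(list(m1, m2))
  expect_equal(agg$ICAC_mean_density_hu, 250)   # unweighted per-artery mean
  pooled <- (200 * 30 + 300 * 3) / 33           # voxel-pooled alternative
  expect_false(isTRUE(all.equal(agg$ICAC_mean_density_hu, pooled)))
  expect_equal(agg$ICAC_volume_mm3, 33 * 1.08)
  expect_identical(as.character(agg$ICAC_category), "300-400")
  expect_true(agg$IAC_present)
  expect_false(agg$VBAC_present)
  expect_identical(agg$VBAC_volume_mm3, 0)
  expect_true(is.na(agg$VBAC_mean_density_hu))
})

test_that("participant category is the maximum over artery categories", {
  m1 <- measure_hu(rep(250, 4), "ICA_left")     # 200-300
  m2 <- measure_hu(rep(450, 4), "vertebral_left")  # 400-600
  agg <- aggregate_participant(list(m1, m2))
  expect_identical(as.character(agg$IAC_category), "400-600")
  expect_identical(as.character(agg$ICAC_category), "200-300")
  expect_identical(as.character(agg$VBAC_category), "400-600")
})

test_that("aggregation rejects unknown or duplicated arteries and handles the
          no-calcification participant", {
  m <- measure_hu(rep(250, 4), "ICA_left")
  bad <- m; bad$artery_id <- "aorta"
  expect_error(aggregate_participant(list(bad)), "unknown artery")
  expect_error(aggregate_participant(list(m, m)), "duplicate")
  quiet <- measure_hu(rep(40, 10), "basilar")
  agg <- aggregate_participant(list(quiet))
  expect_false(agg$IAC_present)
  expect_identical(agg$IAC_volume_mm3, 0)
  expect_true(is.na(agg$IAC_mean_density_hu))
  expect_true(is.na(agg$IAC_category))
})
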