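# Shared fixtures: tiny grids built in code and a randomized phantom
# generator whose inserts are placed on a separated lattice so masks (with
# their soft-tissue margin) never overlap across arteries.

# a 1D-like grid holding the given HU values, with an all-TRUE mask
line_grid <- function(hu, spacing = c(0.6, 0.6, 3.0)) {
  g <- voxel_grid(array(as.integer(hu), dim = c(length(hu), 1, 1)),
                  spacing = spacing)
  list(grid = g, mask = array(TRUE, dim = dim(g$data)))
}

# artery_measurement from a plain HU vector (all voxels in-mask)
measure_hu <- function(hu, artery_id = "ICA_left", spacing = c(0.6, 0.6, 3.0)) {
  lg <- line_grid(hu, spacing)
  threshold_profile(lg$grid, lg$mask, artery_id = artery_id)
}

# randomized multi-insert phantom: 1-3 inserts in distinct arteries at
# lattice slots >= 12 mm apart (radii <= 4 mm + 2 mm margin cannot overlap)
random_phantom <- function(seed) {
  set.seed(seed)
  slots <- expand.grid(x = c(7.5, 21), y = c(7.5, 21), z = c(12, 36))
  n_ins <- sample(1:3, 1)
  pick <- sample(nrow(slots), n_ins)
  arteries <- sample(c("ICA_left", "ICA_right", "vertebral_left",
                       "vertebral_right", "basilar"), n_ins)
  inserts <- lapply(seq_len(n_ins), function(i) {
    ctr <- as.numeric(slots[pick[i], ])
    r <- stats::runif(1, 1.5, 4)
    if (stats::runif(1) < 0.5) {
      prof <- hu_uniform(sample(c(100, 150, 250, 350, 500, 700, 900, 1100), 1))
    } else {
      core <- stats::runif(1, 400, 1300)
      prof <- hu_graded(core, stats::runif(1, 140, 350))
    }
    shape <- sample(c("sphere", "ellipsoid"), 1)
    radii <- if (shape == "sphere") r else r * stats::runif(3, 0.6, 1)
    calc_insert(arteries[i], center_mm = ctr, radii_mm = radii,
                shape = shape, hu_profile = prof)
  })
  generate_phantom(phantom_spec(inserts, seed = seed),
                   grid_shape = c(48L, 48L, 16L), spacing = c(0.6, 0.6, 3.0))
}

# exhaustive-scan detection oracle: plain loop over all voxels
brute_force_detect <- function(grid, mask, threshold) {
  d <- grid$data
  hits <- integer(0)
  for (idx in seq_along(d)) {
    if (mask[idx] && d[idx] >= threshold) hits <- c(hits, idx)
  }
  hits
}

# compare quantify-module output with the truth-table enumeration for every
# artery of a phantom (phantoms from random_phantom have one insert per
# artery, so per-insert truth rows are per-artery truth)
expect_phantom_agreement <- function(phantom) {
  tt <- truth_table(phantom)
  meas <- quantify_phantom(phantom)
  for (r in seq_len(nrow(tt))) {
    m <- meas[[tt$artery_id[r]]]
    floor_row <- m$profile[1, ]
    expect_identical(as.integer(floor_row$voxel_count),
                     as.integer(tt$n_voxels[r]))
    expect_identical(floor_row$volume_mm3, tt$realized_volume_mm3[r])
    expect_identical(floor_row$mean_hu, tt$realized_mean_hu[r])
    expect_identical(as.character(m$density_category),
                     tt$realized_category[r])
  }
}
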