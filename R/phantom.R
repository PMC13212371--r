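# Synthetic CT phantoms: calcific inserts of known geometry and HU profile
# placed in a soft-tissue background, with per-artery masks and exact ground
# truth.  These stand in for real scans (which cannot be redistributed) when
# validating the measurement core.

ARTERY_IDS <- c("ICA_left", "ICA_right", "vertebral_left", "vertebral_right",
                "basilar")

#' Describe a calcific insert
#'
#' An insert is an ellipsoidal (or spherical / shell) region of elevated HU
#' placed inside one of the five intracranial arteries tracked by the
#' pipeline: the paired intracranial carotids (the ICAC bed) and the paired
#' vertebrals plus basilar (the VBAC bed).
#'
#' @param artery_id one of `"ICA_left"`, `"ICA_right"`, `"vertebral_left"`,
#'   `"vertebral_right"`, `"basilar"`.
#' @param center_mm numeric length-3 center in mm.
#' @param radii_mm per-axis semi-axes in mm; a scalar is recycled (sphere).
#' @param shape `"sphere"`, `"ellipsoid"` or `"shell"`. A shell is hollow:
#'   only normalized radii in `(inner_fraction, 1]` belong to the insert.
#' @param hu_profile either `hu_uniform(value)` or
#'   `hu_graded(core_hu, rim_hu)`; graded profiles interpolate linearly in
#'   normalized radius from the core value at the center to the rim value at
#'   the surface (core >= rim, as calcifications are densest centrally).
#' @param inner_fraction for shells, the normalized inner radius (default 0.6).
#' @return A `calc_insert` list carrying the geometry, the profile, and the
#'   analytic `true_volume_mm3` and `true_mean_hu` implied by them.
#' @export
calc_insert <- function(artery_id, center_mm, radii_mm,
                        shape = c("sphere", "ellipsoid", "shell"),
                        hu_profile = hu_uniform(300),
                        inner_fraction = 0.6) {
  shape <- match.arg(shape)
  artery_id <- match.arg(artery_id, ARTERY_IDS)
  radii_mm <- as.numeric(radii_mm)
  if (length(radii_mm) == 1L) radii_mm <- rep(radii_mm, 3L)
  if (length(radii_mm) != 3L || any(radii_mm <= 0))
    stop("`radii_mm` must be one or three strictly positive extents in mm")
  if (shape == "sphere" && length(unique(radii_mm)) != 1L)
    stop("a sphere needs equal radii; use shape = \"ellipsoid\"")
  if (!is.list(hu_profile) || is.null(hu_profile$type))
    stop("`hu_profile` must come from hu_uniform() or hu_graded()")
  if (shape != "shell") inner_fraction <- 0
  if (inner_fraction < 0 || inner_fraction >= 1)
    stop("`inner_fraction` must lie in [0, 1)")

  ell <- 4 / 3 * pi * prod(radii_mm)
  vol <- ell * (1 - inner_fraction^3)
  # Mean HU over the solid: uniform -> value; graded hu(rho) = core +
  # (rim - core) * rho averaged with radial density 3 rho^2 on [f, 1].
  if (hu_profile$type == "uniform") {
    mhu <- hu_profile$value
  } else {
    f <- inner_fraction
    mean_rho <- (3 / 4) * (1 - f^4) / (1 - f^3)
    mhu <- hu_profile$core_hu + (hu_profile$rim_hu - hu_profile$core_hu) * mean_rho
  }
  structure(list(artery_id = artery_id, center_mm = as.numeric(center_mm),
                 shape = shape, radii_mm = radii_mm, hu_profile = hu_profile,
                 inner_fraction = inner_fraction,
                 true_volume_mm3 = vol, true_mean_hu = mhu),
            class = "calc_insert")
}

#' Uniform HU profile
#' @param value HU assigned to every voxel of the insert.
#' @return Profile descriptor for [calc_insert()].
#' @export
hu_uniform <- function(value) {
  if (!is.finite(value)) stop("uniform HU value must be finite")
  list(type = "uniform", value = as.numeric(value))
}

#' Radially graded HU profile
#' @param core_hu HU at the insert center.
#' @param rim_hu HU at the insert surface; must not exceed `core_hu`.
#' @return Profile descriptor for [calc_insert()].
#' @export
hu_graded <- function(core_hu, rim_hu) {
  if (core_hu < rim_hu)
    stop("graded profile requires core_hu >= rim_hu")
  list(type = "graded", core_hu = as.numeric(core_hu),
       rim_hu = as.numeric(rim_hu))
}

#' Specify a phantom
#'
#' Bundles the inserts with the background model and the seed; this is the
#' ground-truth record emitted alongside every generated phantom.
#'
#' @param inserts list of [calc_insert()] objects (possibly empty).
#' @param background_hu_mean,background_hu_sd normal background soft-tissue
#'   HU parameters. Defaults (40, 10) approximate brain parenchyma; draws are
#'   clipped below the 130-HU calcification floor so the background can never
#'   masquerade as calcification.
#' @param seed integer seed governing all phantom randomness.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(inserts = list(), background_hu_mean = 40,
                         background_hu_sd = 10, seed = 1L) {
  if (inherits(inserts, "calc_insert")) inserts <- list(inserts)
  if (!all(vapply(inserts, inherits, logical(1), "calc_insert")))
    stop("`inserts` must be a list of calc_insert objects")
  if (background_hu_sd < 0) stop("background_hu_sd must be >= 0")
  structure(list(inserts = inserts, background_hu_mean = background_hu_mean,
                 background_hu_sd = background_hu_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Normalized squared radius of every voxel center relative to an insert;
# returns an array the size of the grid.
insert_norm_radius2 <- function(ins, dims, spacing, origin, inflate_mm = 0) {
  cx <- axis_centers(dims[1], spacing[1], origin[1])
  cy <- axis_centers(dims[2], spacing[2], origin[2])
  cz <- axis_centers(dims[3], spacing[3], origin[3])
  r <- ins$radii_mm + inflate_mm
  ux <- ((cx - ins$center_mm[1]) / r[1])^2
  uy <- ((cy - ins$center_mm[2]) / r[2])^2
  uz <- ((cz - ins$center_mm[3]) / r[3])^2
  outer(outer(ux, uy, `+`), uz, `+`)
}

insert_membership <- function(ins, dims, spacing, origin) {
  n2 <- insert_norm_radius2(ins, dims, spacing, origin)
  inside <- n2 <= 1
  if (ins$inner_fraction > 0) inside <- inside & n2 > ins$inner_fraction^2
  inside
}

#' Generate a synthetic CT phantom
#'
#' Draws an integer-HU background volume (normal noise, clipped to the CT
#' range and below the 130-HU floor), overwrites each insert's voxels with
#' its HU profile, and builds one binary mask per artery covering its
#' inserts plus a soft-tissue margin. Voxel membership in an insert is
#' decided by whether the voxel center falls inside the shape: the simplest
#' deterministic rule, which also reproduces the partial-volume behaviour of
#' thick-slice CT (boundary voxels flip in or out as resolution changes).
#'
#' @param spec a [phantom_spec()].
#' @param grid_shape integer length-3 array dimensions.
#' @param spacing voxel spacing in mm; the default z spacing is 3 mm.
#' @param mask_margin_mm isotropic margin (mm) added around each insert when
#'   building its artery mask, emulating a region of interest delineated
#'   around the vessel rather than tightly around the calcification.
#' @param seed optional override of `spec$seed`.
#' @return A list with `grid` (a [voxel_grid()]), `masks` (named list of
#'   logical arrays, one per artery with at least one insert), and `spec`.
#' @export
generate_phantom <- function(spec, grid_shape = c(48L, 48L, 16L),
                             spacing = c(0.6, 0.6, 3.0),
                             mask_margin_mm = 2, seed = NULL) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive voxel dimensions in mm")
  dims <- as.integer(grid_shape)
  if (length(dims) != 3L || any(dims < 1L))
    stop("`grid_shape` must be three positive integers")
  extent <- dims * spacing
  for (i in seq_along(spec$inserts)) {
    ins <- spec$inserts[[i]]
    lo <- ins$center_mm - ins$radii_mm
    hi <- ins$center_mm + ins$radii_mm
    if (any(lo < 0) || any(hi > extent))
      stop(sprintf(
        "insert %d (%s) extends outside the grid (extent %.1f x %.1f x %.1f mm)",
        i, ins$artery_id, extent[1], extent[2], extent[3]))
  }
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  set.seed(spec$seed)

  bg <- stats::rnorm(prod(dims), spec$background_hu_mean, spec$background_hu_sd)
  bg <- round(bg)
  bg <- pmin(pmax(bg, HU_MIN), 129)    # below the detection floor by design
  vol <- array(bg, dim = dims)

  origin <- c(0, 0, 0)
  masks <- list()
  for (ins in spec$inserts) {
    inside <- insert_membership(ins, dims, spacing, origin)
    if (ins$hu_profile$type == "uniform") {
      vol[inside] <- round(ins$hu_profile$value)
    } else {
      n2 <- insert_norm_radius2(ins, dims, spacing, origin)
      rho <- sqrt(pmin(n2[inside], 1))
      hu <- ins$hu_profile$core_hu +
        (ins$hu_profile$rim_hu - ins$hu_profile$core_hu) * rho
      vol[inside] <- round(hu)
    }
    roi <- insert_norm_radius2(ins, dims, spacing, origin,
                               inflate_mm = mask_margin_mm) <= 1
    if (is.null(masks[[ins$artery_id]])) {
      masks[[ins$artery_id]] <- roi
    } else {
      masks[[ins$artery_id]] <- masks[[ins$artery_id]] | roi
    }
  }
  vol <- pmin(pmax(vol, HU_MIN), HU_MAX)
  list(grid = voxel_grid(vol, spacing = spacing), masks = masks, spec = spec)
}

#' Realized ground truth of a phantom
#'
#' Recomputes, by direct voxel enumeration in plain loops, what each insert
#' actually deposited in the emitted grid: the number of voxels at or above
#' the 130-HU floor, the realized volume, the realized mean HU over those
#' voxels, and the realized maximum-density category. This enumeration is
#' deliberately written independently of the vectorized measurement code so
#' the two act as cross-checking implementations of the same counting.
#'
#' @param phantom result of [generate_phantom()].
#' @param floor_hu detection floor, default 130 HU.
#' @return `data.frame` with one row per insert: `insert`, `artery_id`,
#'   `n_voxels`, `realized_volume_mm3`, `realized_mean_hu` (NA when no voxel
#'   reaches the floor), `realized_max_hu`, `realized_category`.
#' @export
truth_table <- function(phantom, floor_hu = 130) {
  if (!is.list(phantom) || !inherits(phantom$grid, "voxel_grid"))
    stop("`phantom` must be the output of generate_phantom()")
  grid <- phantom$grid
  dims <- dim(grid$data)
  vv <- voxel_volume(grid$spacing)
  inserts <- phantom$spec$inserts
  out <- data.frame(insert = integer(0), artery_id = character(0),
                    n_voxels = integer(0), realized_volume_mm3 = numeric(0),
                    realized_mean_hu = numeric(0), realized_max_hu = numeric(0),
                    realized_category = character(0),
                    stringsAsFactors = FALSE)
  for (i in seq_along(inserts)) {
    ins <- inserts[[i]]
    # explicit per-axis loop over voxel centers (the slow, obvious oracle)
    n <- 0L; s <- 0; mx <- -Inf
    f2 <- ins$inner_fraction^2
    for (k in seq_len(dims[3])) {
      z <- (k - 0.5) * grid$spacing[3]
      uz <- ((z - ins$center_mm[3]) / ins$radii_mm[3])^2
      if (uz > 1) next
      for (j in seq_len(dims[2])) {
        y <- (j - 0.5) * grid$spacing[2]
        uy <- ((y - ins$center_mm[2]) / ins$radii_mm[2])^2
        if (uz + uy > 1) next
        for (ii in seq_len(dims[1])) {
          x <- (ii - 0.5) * grid$spacing[1]
          u <- uz + uy + ((x - ins$center_mm[1]) / ins$radii_mm[1])^2
          if (u > 1 || u <= f2) next
          hu <- grid$data[ii, j, k]
          if (hu >= floor_hu) {
            n <- n + 1L
            s <- s + hu
            if (hu > mx) mx <- hu
          }
        }
      }
    }
    out[i, "insert"] <- i
    out[i, "artery_id"] <- ins$artery_id
    out[i, "n_voxels"] <- n
    out[i, "realized_volume_mm3"] <- n * vv
    out[i, "realized_mean_hu"] <- if (n > 0) s / n else NA_real_
    out[i, "realized_max_hu"] <- if (n > 0) mx else NA_real_
    out[i, "realized_category"] <- if (n > 0)
      as.character(assign_density_category(mx)) else NA_character_
  }
  out
}

#' Write a phantom to disk
#'
#' The grid and each artery mask go out as NIfTI-1 volumes (spacing in the
#' affine); the realized truth table as CSV.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory, created if needed.
#' @return Named character vector of written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(grid = file.path(dir, "phantom.nii.gz"))
  write_volume_nifti(phantom$grid, paths[["grid"]])
  for (a in names(phantom$masks)) {
    p <- file.path(dir, sprintf("mask_%s.nii.gz", a))
    write_volume_nifti(phantom$masks[[a]], p, spacing = phantom$grid$spacing)
    paths[[paste0("mask_", a)]] <- p
  }
  tt <- truth_table(phantom)
  paths[["truth"]] <- file.path(dir, "truth_table.csv")
  utils::write.csv(tt, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
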