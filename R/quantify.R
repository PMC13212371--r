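# Measurement core: in-mask voxel detection above an HU threshold, mean
# density, volume, the threshold ladder, maximum-density categorization and
# participant-level aggregation over arterial beds.
#
# Conventions (calcium-scoring standard on non-contrast CT):
#   * detection floor 130 HU, inclusive ("HU >= 130");
#   * volume = supra-floor voxel count x voxel volume (no lesion-size or
#     connected-component filtering -- any supra-threshold in-mask voxel
#     counts);
#   * density absent (NA), not zero, when no voxel reaches the floor.

DENSITY_CATEGORY_LABELS <- c("130-200", "200-300", "300-400", "400-600",
                             "600-800", "800-1000", ">1000")

#' HU threshold ladder
#'
#' The ordered set of thresholds at which volume and density are re-measured
#' to profile increasingly dense calcification components. The first element
#' is the detection floor.
#'
#' @param thresholds strictly increasing HU values; default
#'   `c(130, 200, 300, 400, 600, 800, 1000)`.
#' @return Numeric vector of class `threshold_ladder`.
#' @export
threshold_ladder <- function(thresholds = c(130, 200, 300, 400, 600, 800, 1000)) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || any(!is.finite(thresholds)))
    stop("`thresholds` must be finite HU values")
  if (any(diff(thresholds) <= 0))
    stop("`thresholds` must be strictly increasing")
  if (thresholds[1] < 0) stop("thresholds must be non-negative HU")
  structure(thresholds, class = "threshold_ladder")
}

#' Detect supra-threshold voxels within a mask
#'
#' @param grid a [voxel_grid()].
#' @param mask logical (or 0/1) array with the same dimensions as the grid.
#' @param threshold HU threshold; a voxel with HU exactly equal to the
#'   threshold is included (the floor is inclusive).
#' @return Integer vector of linear voxel indices into `grid$data`.
#' @export
detect_voxels <- function(grid, mask, threshold = 130) {
  if (!inherits(grid, "voxel_grid")) stop("`grid` must be a voxel_grid")
  if (!identical(dim(mask), dim(grid$data)))
    stop("mask dimensions do not match the grid")
  if (!is.finite(threshold) || threshold < 0)
    stop("`threshold` must be a non-negative HU value")
  which(as.logical(mask) & grid$data >= threshold)
}

#' Mean density over a voxel set
#'
#' The arithmetic mean of HU over the detected voxels: sum of HU values
#' divided by their count. Absent (NA) for an empty set -- an artery without
#' supra-floor voxels has no density, rather than density zero.
#'
#' @param grid a [voxel_grid()].
#' @param voxels linear indices from [detect_voxels()].
#' @return Mean HU, or `NA_real_` when `voxels` is empty.
#' @export
mean_density <- function(grid, voxels) {
  if (!inherits(grid, "voxel_grid")) stop("`grid` must be a voxel_grid")
  if (length(voxels) == 0L) return(NA_real_)
  sum(as.numeric(grid$data[voxels])) / length(voxels)
}

#' Calcification volume of a voxel set
#'
#' @param voxels linear voxel indices (or anything with a `length`).
#' @param spacing voxel spacing in mm, or a [voxel_grid()].
#' @return Volume in mm^3: voxel count times voxel volume.
#' @export
calc_volume <- function(voxels, spacing) {
  length(voxels) * voxel_volume(spacing)
}

#' Per-artery threshold-ladder profile
#'
#' Repeats the volume and density measurement at every ladder threshold and
#' records the maximum in-mask HU (at or above the floor) together with its
#' density category.
#'
#' @param grid a [voxel_grid()].
#' @param mask binary array, same shape as the grid.
#' @param ladder a [threshold_ladder()].
#' @param artery_id optional label carried into the result.
#' @return An `artery_measurement`: list with `artery_id`, `profile` (a
#'   `data.frame` of `threshold`, `voxel_count`, `volume_mm3`, `mean_hu`),
#'   `max_hu` (NA when nothing reaches the floor) and `density_category`
#'   (ordered factor, NA when absent).
#' @export
threshold_profile <- function(grid, mask, ladder = threshold_ladder(),
                              artery_id = NA_character_) {
  if (!inherits(ladder, "threshold_ladder")) ladder <- threshold_ladder(ladder)
  floor_idx <- detect_voxels(grid, mask, ladder[1])
  vv <- voxel_volume(grid$spacing)
  prof <- data.frame(threshold = as.numeric(ladder),
                     voxel_count = NA_integer_,
                     volume_mm3 = NA_real_,
                     mean_hu = NA_real_)
  if (length(floor_idx)) {
    hu <- as.numeric(grid$data[floor_idx])
    for (r in seq_along(ladder)) {
      keep <- hu >= ladder[r]
      n <- sum(keep)
      prof$voxel_count[r] <- n
      prof$volume_mm3[r] <- n * vv
      prof$mean_hu[r] <- if (n > 0) sum(hu[keep]) / n else NA_real_
    }
    max_hu <- max(hu)
  } else {
    prof$voxel_count <- 0L
    prof$volume_mm3 <- 0
    max_hu <- NA_real_
  }
  structure(list(artery_id = artery_id, profile = prof, max_hu = max_hu,
                 density_category = assign_density_category(max_hu)),
            class = "artery_measurement")
}

#' @export
print.artery_measurement <- function(x, ...) {
  cat(sprintf("<artery_measurement> %s  max HU: %s  category: %s\n",
              x$artery_id,
              ifelse(is.na(x$max_hu), "absent", format(x$max_hu)),
              ifelse(is.na(x$density_category), "absent",
                     as.character(x$density_category))))
  print(x$profile)
  invisible(x)
}

#' Assign the 7-level maximum-density category
#'
#' Bins are left-closed / right-open -- 130-200, 200-300, 300-400, 400-600,
#' 600-800 -- except at the top of the ladder: the printed labels make
#' ">1000" strictly exclusive, so 1000 HU itself falls in "800-1000". A
#' boundary value such as 200 HU belongs to "200-300".
#'
#' @param max_hu maximum HU observed (vectorized); `NA` for no calcification.
#' @return Ordered factor over the seven labels, `NA` where `max_hu` is `NA`.
#' @export
assign_density_category <- function(max_hu) {
  max_hu <- as.numeric(max_hu)
  if (any(!is.na(max_hu) & max_hu < 130))
    stop("max_hu below the 130-HU floor: pass NA for arteries without calcification")
  lev <- ifelse(is.na(max_hu), NA_integer_,
                ifelse(max_hu > 1000, 7L,
                       findInterval(max_hu, c(130, 200, 300, 400, 600, 800))))
  factor(DENSITY_CATEGORY_LABELS[lev], levels = DENSITY_CATEGORY_LABELS,
         ordered = TRUE)
}

#' Default artery-to-bed map
#'
#' The paired intracranial carotids form the ICAC bed; the paired vertebrals
#' and the basilar form the VBAC bed. IAC is the union of both.
#'
#' @return Named character vector: artery id -> `"ICAC"` or `"VBAC"`.
#' @export
artery_bed_map <- function() {
  c(ICA_left = "ICAC", ICA_right = "ICAC", vertebral_left = "VBAC",
    vertebral_right = "VBAC", basilar = "VBAC")
}

#' Aggregate artery measurements to the participant level
#'
#' Bed-level average density is the unweighted mean of the per-artery mean
#' densities over affected arteries (each artery contributes equally,
#' regardless of its voxel count); bed volume sums per-artery volumes at the
#' detection floor; the bed density category is the maximum of the per-artery
#' categories. IAC aggregates apply the same rules over all five arteries.
#'
#' @param measurements list of `artery_measurement` objects, one per artery.
#' @param bed_map named vector mapping artery ids to beds; see
#'   [artery_bed_map()].
#' @return One-row `data.frame` with, for each of `IAC`, `ICAC`, `VBAC`:
#'   `<bed>_present`, `<bed>_n_affected`, `<bed>_volume_mm3`,
#'   `<bed>_mean_density_hu` (NA if no affected artery) and `<bed>_category`.
#' @export
aggregate_participant <- function(measurements, bed_map = artery_bed_map()) {
  if (inherits(measurements, "artery_measurement"))
    measurements <- list(measurements)
  ids <- vapply(measurements, function(m) m$artery_id, character(1))
  if (anyNA(ids)) stop("every measurement needs an artery_id")
  if (anyDuplicated(ids)) stop("duplicate artery_id in measurements")
  unknown <- setdiff(ids, names(bed_map))
  if (length(unknown))
    stop("unknown artery id(s): ", paste(unknown, collapse = ", "))

  floor_row <- function(m) m$profile[1, ]
  per <- data.frame(
    artery_id = ids,
    bed = unname(bed_map[ids]),
    volume_mm3 = vapply(measurements, function(m) floor_row(m)$volume_mm3,
                        numeric(1)),
    mean_hu = vapply(measurements, function(m) floor_row(m)$mean_hu,
                     numeric(1)),
    cat_level = vapply(measurements, function(m)
      if (is.na(m$density_category)) NA_integer_
      else as.integer(m$density_category), integer(1)),
    stringsAsFactors = FALSE)

  one_bed <- function(rows) {
    affected <- !is.na(rows$mean_hu)
    n_aff <- sum(affected)
    lvl <- if (n_aff > 0) max(rows$cat_level[affected]) else NA_integer_
    data.frame(
      present = n_aff > 0,
      n_affected = n_aff,
      volume_mm3 = sum(rows$volume_mm3),
      mean_density_hu = if (n_aff > 0) mean(rows$mean_hu[affected]) else NA_real_,
      category = factor(
        if (is.na(lvl)) NA_character_ else DENSITY_CATEGORY_LABELS[lvl],
        levels = DENSITY_CATEGORY_LABELS, ordered = TRUE))
  }
  beds <- list(IAC = per, ICAC = per[per$bed == "ICAC", ],
               VBAC = per[per$bed == "VBAC", ])
  out <- do.call(cbind, lapply(names(beds), function(b) {
    d <- one_bed(beds[[b]])
    names(d) <- paste(b, names(d), sep = "_")
    d
  }))
  rownames(out) <- NULL
  out
}

#' Quantify every artery of a phantom
#'
#' Convenience wrapper running [threshold_profile()] over each artery mask.
#'
#' @param phantom output of [generate_phantom()], or a list with `grid` and
#'   `masks`.
#' @param ladder a [threshold_ladder()].
#' @return Named list of `artery_measurement` objects.
#' @export
quantify_phantom <- function(phantom, ladder = threshold_ladder()) {
  stats::setNames(
    lapply(names(phantom$masks), function(a)
      threshold_profile(phantom$grid, phantom$masks[[a]], ladder,
                        artery_id = a)),
    names(phantom$masks))
}

#' Flatten artery measurements to a long table
#'
#' @param measurements list of `artery_measurement` objects.
#' @param participant_id optional id column value.
#' @return Long `data.frame`: participant_id, artery_id, threshold,
#'   voxel_count, volume_mm3, mean_hu, max_hu, category.
#' @export
measurements_table <- function(measurements, participant_id = NA) {
  if (inherits(measurements, "artery_measurement"))
    measurements <- list(measurements)
  do.call(rbind, lapply(measurements, function(m) {
    cbind(data.frame(participant_id = participant_id,
                     artery_id = m$artery_id),
          m$profile,
          data.frame(max_hu = m$max_hu,
                     category = as.character(m$density_category)))
  }))
}
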