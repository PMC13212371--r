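# VoxelGrid: the imaging substrate -- a 3D array of integer Hounsfield units
# plus physical voxel spacing.  HU range is the CT storage convention
# (-1024 .. 3071); non-contrast head CT in this pipeline uses ~3 mm slices.

HU_MIN <- -1024L
HU_MAX <- 3071L

#' Construct a voxel grid
#'
#' A `voxel_grid` couples a 3D array of Hounsfield-unit (HU) intensities with
#' the physical voxel spacing, the minimal substrate needed for in-mask
#' volume and density measurement.
#'
#' @param data 3D numeric array of HU values. Values must lie within the CT
#'   storage range (-1024 to 3071 HU); they are stored as integers, matching
#'   how CT scanners store attenuation.
#' @param spacing numeric length-3, voxel edge lengths `(dx, dy, dz)` in mm.
#'   All strictly positive. Default z spacing of 3 mm mirrors the slice
#'   thickness typical of non-contrast head CT used for calcification scoring.
#' @param origin numeric length-3, position of the first voxel corner in mm.
#' @return An object of class `voxel_grid`: a list with elements `data`
#'   (integer 3D array), `spacing`, and `origin`.
#' @export
voxel_grid <- function(data, spacing = c(0.6, 0.6, 3.0), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array of HU values")
  if (any(dim(data) < 1L))
    stop("`data` must be non-empty along every axis")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive voxel dimensions in mm")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite coordinates in mm")
  rng <- range(data)
  if (rng[1] < HU_MIN || rng[2] > HU_MAX)
    stop(sprintf("HU values outside the CT range [%d, %d]", HU_MIN, HU_MAX))
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range: %d .. %d\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel volume of a grid
#'
#' @param spacing a `voxel_grid` or a length-3 spacing vector in mm.
#' @return Volume of a single voxel in mm^3.
#' @export
voxel_volume <- function(spacing) {
  if (inherits(spacing, "voxel_grid")) spacing <- spacing$spacing
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive voxel dimensions in mm")
  prod(spacing)
}

# Physical coordinates (mm) of voxel centers along one axis: voxel i spans
# [(i-1)*d, i*d), its center sits at (i - 0.5)*d + origin.
axis_centers <- function(n, d, o) (seq_len(n) - 0.5) * d + o

#' Write a voxel grid or mask as NIfTI-1
#'
#' Spacing is stored in the NIfTI affine (diagonal scaling), so round-trips
#' preserve physical geometry.
#'
#' @param x a `voxel_grid`, or a 3D logical/integer mask array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing spacing override for bare mask arrays (ignored for grids).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path, spacing = NULL) {
  if (inherits(x, "voxel_grid")) {
    arr <- x$data
    spacing <- x$spacing
  } else {
    arr <- x
    storage.mode(arr) <- "integer"
    if (is.null(spacing)) stop("`spacing` is required when writing a bare mask")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- as.numeric(spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a voxel grid
#'
#' @param path NIfTI file path.
#' @return A `voxel_grid` with spacing taken from the file header.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  voxel_grid(array(as.integer(round(img)), dim = dim(img)[1:3]), spacing = sp)
}
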