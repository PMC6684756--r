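#' Planned dose grid
#'
#' A 3D scalar dose distribution on a regular voxel lattice, together with
#' the geometric metadata needed to map voxel indices to patient ("world")
#' coordinates. World coordinates are voxel centers:
#' `x_k = origin_mm[k] + index * spacing_mm[k]` with 0-based indices.
#' Exactly one grid axis is designated as the patient lateral (left-right)
#' axis; dose-gradient features are taken along it.
#'
#' @param values Numeric 3D array of dose in Gy; finite and non-negative.
#' @param spacing_mm Numeric length-3, voxel size per grid axis in mm.
#' @param origin_mm Numeric length-3, world coordinate of voxel (0,0,0).
#' @param lateral_axis Integer in 1:3, which grid axis runs left-right.
#' @return An object of class `dose_grid`.
#' @seealso [structure_mask()], [compute_md()], [compute_gradx()]
#' @export
dose_grid <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                      lateral_axis = 1L) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!all(is.finite(values)) || any(values < 0))
    stop("dose values must be finite and non-negative")
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive finite numbers")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be 3 finite numbers")
  lateral_axis <- as.integer(lateral_axis)
  if (!lateral_axis %in% 1:3) stop("`lateral_axis` must be 1, 2 or 3")
  axis_labels <- rep("in-plane", 3L)
  axis_labels[lateral_axis] <- "lateral"
  structure(
    list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm,
         lateral_axis = lateral_axis, axis_labels = axis_labels),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing_mm, 4), collapse = "/"),
      " mm, lateral axis ", x$lateral_axis, "\n", sep = "")
  cat("  dose range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "] Gy\n", sep = "")
  invisible(x)
}

#' Binary structure mask
#'
#' A binary region (e.g. a parotid gland) on the same lattice as its dose
#' grid. `medial_direction` records which way along the lateral axis points
#' toward the patient midline (+1: increasing index is medial), so that
#' lateral dose gradients can be reported with a medial-positive sign for
#' either gland.
#'
#' @param values Logical or 0/1 3D array; must contain at least one voxel.
#' @param spacing_mm,origin_mm,lateral_axis Lattice metadata, as in
#'   [dose_grid()].
#' @param laterality `"contralateral"` or `"ipsilateral"` (relative to the
#'   tumour side).
#' @param medial_direction +1 or -1: grid direction toward the midline.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(values, spacing_mm, origin_mm = c(0, 0, 0),
                           lateral_axis = 1L,
                           laterality = c("contralateral", "ipsilateral"),
                           medial_direction = 1L) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (is.numeric(values)) {
    if (!all(values %in% c(0, 1))) stop("mask values must be 0/1 or logical")
    values <- array(values > 0.5, dim(values))
  }
  if (!is.logical(values)) stop("mask values must be 0/1 or logical")
  if (anyNA(values)) stop("mask values must not contain NA")
  if (!any(values)) stop("mask is empty: at least one voxel required")
  laterality <- match.arg(laterality)
  medial_direction <- as.integer(medial_direction)
  if (!medial_direction %in% c(-1L, 1L))
    stop("`medial_direction` must be +1 or -1")
  g <- dose_grid(array(0, dim(values)), spacing_mm, origin_mm, lateral_axis)
  structure(
    list(values = values, spacing_mm = g$spacing_mm,
         origin_mm = g$origin_mm, lateral_axis = g$lateral_axis,
         laterality = laterality, medial_direction = medial_direction),
    class = "structure_mask"
  )
}

#' @export
print.structure_mask <- function(x, ...) {
  cat("<structure_mask> ", sum(x$values), " of ",
      length(x$values), " voxels, ", x$laterality,
      ", medial direction ", sprintf("%+d", x$medial_direction),
      " along axis ", x$lateral_axis, "\n", sep = "")
  invisible(x)
}

# world coordinates of voxel centers along one axis (0-based indices)
voxel_centers <- function(x, axis) {
  n <- dim(x$values)[axis]
  x$origin_mm[axis] + (seq_len(n) - 1) * x$spacing_mm[axis]
}

# grids/masks must share dim, spacing, origin and lateral axis
check_same_lattice <- function(grid, mask) {
  if (!identical(dim(grid$values), dim(mask$values)))
    stop("dose grid and mask have different dimensions")
  if (max(abs(grid$spacing_mm - mask$spacing_mm)) > 1e-9 ||
      max(abs(grid$origin_mm - mask$origin_mm)) > 1e-9)
    stop("dose grid and mask are on different lattices (spacing/origin)")
  if (grid$lateral_axis != mask$lateral_axis)
    stop("dose grid and mask disagree on the lateral axis")
  invisible(TRUE)
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} for exchanging dose grids and masks
#' with treatment-planning exports. Spacing is taken from the NIfTI
#' `pixdim`; the lateral axis and medial direction are not stored in the
#' NIfTI header and must be supplied by the caller.
#'
#' @param x A [dose_grid()] or [structure_mask()].
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @return `write_volume_nifti()` returns `path` invisibly;
#'   `read_dose_grid()` a `dose_grid`; `read_structure_mask()` a
#'   `structure_mask`.
#' @export
write_volume_nifti <- function(x, path) {
  stopifnot(inherits(x, "dose_grid") || inherits(x, "structure_mask"))
  vals <- if (is.logical(x$values)) array(as.integer(x$values), dim(x$values))
          else x$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @param origin_mm,lateral_axis,laterality,medial_direction Metadata not
#'   representable in the NIfTI header, as in [dose_grid()] /
#'   [structure_mask()].
#' @export
read_dose_grid <- function(path, origin_mm = c(0, 0, 0), lateral_axis = 1L) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  dose_grid(arr, RNifti::pixdim(img)[1:3], origin_mm, lateral_axis)
}

#' @rdname write_volume_nifti
#' @export
read_structure_mask <- function(path, origin_mm = c(0, 0, 0),
                                lateral_axis = 1L,
                                laterality = "contralateral",
                                medial_direction = 1L) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  structure_mask(arr > 0.5, RNifti::pixdim(img)[1:3], origin_mm,
                 lateral_axis, laterality, medial_direction)
}
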