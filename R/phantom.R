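#' Analytic dose phantom specification
#'
#' Describes a phantom emulating a highly conformal head-and-neck plan in
#' the neighbourhood of a parotid gland: the dose rises along the lateral
#' axis toward the midline target through a logistic (sigmoid) falloff,
#' and the gland is an ellipsoid sitting on the falloff flank. The phantom
#' has a known analytic gradient everywhere, which makes it a ground-truth
#' fixture for dose-feature extraction and for delivered-dose accumulation
#' under migration.
#'
#' @param grid_shape Integer length-3, voxel counts per axis (all >= 3).
#' @param spacing_mm Numeric length-3, voxel size in mm (all > 0).
#' @param plateau_dose_gy Target-region plateau dose in Gy.
#' @param falloff_center_mm Lateral world coordinate of the 50% dose point.
#' @param falloff_scale_mm Logistic scale of the falloff (> 0); smaller is
#'   steeper.
#' @param gland_center_mm Numeric length-3, ellipsoid center (world mm).
#' @param gland_radii_mm Numeric length-3, ellipsoid semi-axes in mm.
#' @param medial_axis Grid axis (1:3) that runs left-right.
#' @param medial_direction +1/-1, grid direction toward the midline.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec()
#' dose <- make_phantom_dose(spec)
#' gland <- make_gland_mask(spec)
#' compute_md(dose, gland)
#' @export
phantom_spec <- function(grid_shape = c(80, 40, 20),
                         spacing_mm = c(1, 2, 2),
                         plateau_dose_gy = 40,
                         falloff_center_mm = 32,
                         falloff_scale_mm = 7,
                         gland_center_mm = c(30, 40, 20),
                         gland_radii_mm = c(12, 15, 12),
                         medial_axis = 1L,
                         medial_direction = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 3L))
    stop("`grid_shape` must be 3 counts, all >= 3")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers")
  if (!is.finite(plateau_dose_gy) || plateau_dose_gy <= 0)
    stop("`plateau_dose_gy` must be positive")
  if (!is.finite(falloff_scale_mm) || falloff_scale_mm <= 0)
    stop("`falloff_scale_mm` must be positive")
  if (length(gland_center_mm) != 3L || length(gland_radii_mm) != 3L ||
      any(!is.finite(gland_center_mm)) || any(gland_radii_mm <= 0))
    stop("gland center/radii must be 3 finite numbers, radii positive")
  medial_axis <- as.integer(medial_axis)
  if (!medial_axis %in% 1:3) stop("`medial_axis` must be 1, 2 or 3")
  medial_direction <- as.integer(medial_direction)
  if (!medial_direction %in% c(-1L, 1L))
    stop("`medial_direction` must be +1 or -1")
  extent <- (grid_shape - 1) * spacing_mm
  if (any(gland_center_mm - gland_radii_mm < 0) ||
      any(gland_center_mm + gland_radii_mm > extent))
    stop("gland ellipsoid must lie fully inside the grid")
  structure(
    list(grid_shape = grid_shape, spacing_mm = spacing_mm,
         plateau_dose_gy = plateau_dose_gy,
         falloff_center_mm = falloff_center_mm,
         falloff_scale_mm = falloff_scale_mm,
         gland_center_mm = as.numeric(gland_center_mm),
         gland_radii_mm = as.numeric(gland_radii_mm),
         medial_axis = medial_axis, medial_direction = medial_direction),
    class = "phantom_spec"
  )
}

#' Build the phantom dose grid
#'
#' Dose varies only along the lateral axis:
#' `D(x) = plateau * sigma((x - falloff_center) * medial_direction / scale)`
#' with `sigma` the logistic function, so the dose climbs toward the
#' midline and equals half the plateau at the falloff center.
#'
#' @param spec A [phantom_spec()].
#' @return A [dose_grid()].
#' @export
make_phantom_dose <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- (seq_len(spec$grid_shape[spec$medial_axis]) - 1) *
    spec$spacing_mm[spec$medial_axis]
  prof <- spec$plateau_dose_gy *
    stats::plogis((x - spec$falloff_center_mm) * spec$medial_direction /
                    spec$falloff_scale_mm)
  idx <- slice.index(array(0, spec$grid_shape), spec$medial_axis)
  dose_grid(array(prof[idx], spec$grid_shape), spec$spacing_mm,
            lateral_axis = spec$medial_axis)
}

#' Build the phantom gland mask
#'
#' A voxel belongs to the gland iff its center lies inside the ellipsoid
#' defined by `gland_center_mm` / `gland_radii_mm`.
#'
#' @param spec A [phantom_spec()].
#' @param laterality Passed to [structure_mask()].
#' @return A [structure_mask()].
#' @export
make_gland_mask <- function(spec, laterality = "contralateral") {
  stopifnot(inherits(spec, "phantom_spec"))
  q <- array(0, spec$grid_shape)
  for (ax in 1:3) {
    c_ax <- (seq_len(spec$grid_shape[ax]) - 1) * spec$spacing_mm[ax]
    term <- ((c_ax - spec$gland_center_mm[ax]) / spec$gland_radii_mm[ax])^2
    q <- q + term[slice.index(q, ax)]
  }
  inside <- q <= 1
  if (!any(inside)) stop("gland mask is empty on this lattice")
  structure_mask(inside, spec$spacing_mm, lateral_axis = spec$medial_axis,
                 laterality = laterality,
                 medial_direction = spec$medial_direction)
}

#' Linear migration trajectory over a treatment course
#'
#' Inter-fraction parotid migration is modelled as equal for both glands
#' and linear in time: at day `t` the gland has moved
#' `shift_mm_per_day * t` mm toward the midline.
#'
#' @param fraction_days Strictly increasing acquisition days; first must
#'   be 0 (fraction 1).
#' @param shift_mm_per_day Medial migration rate in mm/day.
#' @return An object of class `course_trajectory` with the total shift at
#'   the last fraction precomputed.
#' @export
course_trajectory <- function(fraction_days, shift_mm_per_day) {
  fraction_days <- as.numeric(fraction_days)
  if (length(fraction_days) < 1L || fraction_days[1] != 0 ||
      any(diff(fraction_days) <= 0))
    stop("`fraction_days` must be strictly increasing and start at 0")
  if (!is.finite(shift_mm_per_day)) stop("`shift_mm_per_day` must be finite")
  structure(
    list(fraction_days = fraction_days,
         shift_mm_per_day = shift_mm_per_day,
         total_shift_mm = shift_mm_per_day * fraction_days[length(fraction_days)]),
    class = "course_trajectory"
  )
}

# translate a logical array by k voxels along one axis; errors if any
# in-mask voxel would leave the grid
translate_mask_array <- function(values, k, axis) {
  if (k == 0) return(values)
  dims <- dim(values)
  idx <- which(values, arr.ind = TRUE)
  shifted <- idx[, axis] + k
  if (any(shifted < 1L | shifted > dims[axis]))
    stop("mask leaves the grid under the requested translation")
  idx[, axis] <- shifted
  out <- array(FALSE, dims)
  out[idx] <- TRUE
  out
}

#' Simulate a migrating gland over the treatment course
#'
#' Translates the gland mask medially by `shift_mm_per_day * day`,
#' rounded to the nearest whole voxel, for every acquisition day. The
#' translation preserves the voxel count; a shift that would push the
#' gland off the grid is an error.
#'
#' @param mask A [structure_mask()] at fraction 1.
#' @param trajectory A [course_trajectory()].
#' @return A list of `structure_mask` objects, one per fraction day.
#' @export
simulate_course <- function(mask, trajectory) {
  stopifnot(inherits(mask, "structure_mask"),
            inherits(trajectory, "course_trajectory"))
  h <- mask$spacing_mm[mask$lateral_axis]
  lapply(trajectory$fraction_days, function(t) {
    k <- as.integer(round(trajectory$shift_mm_per_day * t / h)) *
      mask$medial_direction
    out <- mask
    out$values <- translate_mask_array(mask$values, k, mask$lateral_axis)
    out
  })
}
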