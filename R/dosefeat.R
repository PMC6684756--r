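#' Mean structure dose (MD)
#'
#' Arithmetic mean of the planned dose over the in-mask voxels. Voxels
#' have uniform volume, so no weighting is needed; the mask must share
#' the dose grid's lattice (no resampling is performed, by design).
#'
#' @param grid A [dose_grid()].
#' @param mask A [structure_mask()] on the same lattice.
#' @return Mean dose in Gy.
#' @export
compute_md <- function(grid, mask) {
  stopifnot(inherits(grid, "dose_grid"), inherits(mask, "structure_mask"))
  check_same_lattice(grid, mask)
  mean(grid$values[mask$values])
}

# per-voxel derivative along `axis` by central differences, one-sided at
# the two boundary planes; exact for fields affine in the axis coordinate
finite_diff_axis <- function(values, spacing, axis) {
  n <- dim(values)[axis]
  if (n < 3L) stop("grid must have at least 3 voxels along the lateral axis")
  take <- function(i) {
    idx <- rep(list(quote(expr = )), 3L)
    idx[[axis]] <- i
    do.call(`[`, c(list(values), idx, list(drop = FALSE)))
  }
  interior <- (take(3:n) - take(1:(n - 2))) / (2 * spacing)
  lo <- (take(2L) - take(1L)) / spacing
  hi <- (take(n) - take(n - 1L)) / spacing
  out <- array(0, dim(values))
  assign_slab <- function(i, val) {
    idx <- rep(list(quote(expr = )), 3L)
    idx[[axis]] <- i
    do.call(`[<-`, c(list(out), idx, list(value = val)))
  }
  out <- assign_slab(2:(n - 1), interior)
  out <- assign_slab(1L, lo)
  out <- assign_slab(n, hi)
  out
}

#' Average lateral dose gradient (GRADX)
#'
#' Per-voxel derivative of the dose along the lateral axis (central
#' differences; one-sided stencils at the grid boundary), signed so that
#' positive means dose increasing toward the patient midline (the raw
#' derivative is multiplied by the mask's `medial_direction`), then
#' averaged over the in-mask voxels. With `absolute = TRUE` the mean of
#' the unsigned derivative magnitudes is returned instead and the sign
#' convention plays no role.
#'
#' @inheritParams compute_md
#' @param absolute Average `|dD/dx|` instead of the signed derivative.
#' @return Average gradient in Gy/mm (medial-positive when signed).
#' @export
compute_gradx <- function(grid, mask, absolute = FALSE) {
  stopifnot(inherits(grid, "dose_grid"), inherits(mask, "structure_mask"))
  check_same_lattice(grid, mask)
  ax <- grid$lateral_axis
  deriv <- finite_diff_axis(grid$values, grid$spacing_mm[ax], ax)
  if (absolute) return(mean(abs(deriv[mask$values])))
  mean(deriv[mask$values]) * mask$medial_direction
}

#' Planned dose features of a structure
#'
#' Convenience wrapper returning MD, GRADX and the mask size in one row,
#' ready to be bound into a cohort feature table.
#'
#' @inheritParams compute_gradx
#' @return A one-row data.frame with `md_gy`, `gradx_gy_per_mm`,
#'   `n_voxels`, `laterality`.
#' @export
dose_features <- function(grid, mask, absolute = FALSE) {
  data.frame(
    md_gy = compute_md(grid, mask),
    gradx_gy_per_mm = compute_gradx(grid, mask, absolute = absolute),
    n_voxels = sum(mask$values),
    laterality = mask$laterality,
    stringsAsFactors = FALSE
  )
}

#' Delivered mean dose over a migrating structure
#'
#' The dose grid is fixed (the plan is not re-optimised) while the
#' structure migrates; the delivered mean dose is the unweighted average
#' over fractions of the planned mean dose evaluated on each fraction's
#' mask. For a smooth dose field and linear migration totalling PGM mm,
#' a first-order expansion gives
#' `delivered - planned ~= GRADX * PGM / 2`,
#' which is the mechanistic rationale for using GRADX and PGM as
#' xerostomia risk factors.
#'
#' @param grid A [dose_grid()].
#' @param masks Non-empty list of [structure_mask()] objects, one per
#'   fraction, all on the grid's lattice.
#' @return Delivered mean dose in Gy.
#' @export
accumulate_delivered_md <- function(grid, masks) {
  if (!is.list(masks) || length(masks) == 0L)
    stop("`masks` must be a non-empty list of structure masks")
  mean(vapply(masks, function(m) compute_md(grid, m), numeric(1)))
}
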