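#' Slab volume of a binary mask
#'
#' Volume of an axial slab segmentation (e.g. the external contour at the
#' C2 vertebral body level): voxel count times voxel volume, in mL.
#'
#' @param mask A [structure_mask()] (or any list with logical `values`
#'   and `spacing_mm`).
#' @return Volume in mL.
#' @export
slab_volume <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$values) * prod(mask$spacing_mm) / 1000
}

#' Relative external-contour volume change at C2
#'
#' `delta_vc2(v1, vc)` returns `100 * (vc - v1) / v1`, the percent change
#' of the C2-level external-contour volume between fraction 1 and the
#' control day. Weight loss during treatment shrinks the contour, so
#' typical values are negative.
#'
#' @param vc2_first_ml Baseline (fraction 1) slab volume in mL; > 0.
#' @param vc2_control_ml Control-day slab volume in mL.
#' @return Percent change (vectorised).
#' @export
delta_vc2 <- function(vc2_first_ml, vc2_control_ml) {
  if (any(!is.finite(vc2_first_ml)) || any(vc2_first_ml <= 0))
    stop("baseline volume `vc2_first_ml` must be positive")
  if (any(!is.finite(vc2_control_ml)))
    stop("`vc2_control_ml` must be finite")
  100 * (vc2_control_ml - vc2_first_ml) / vc2_first_ml
}

#' Migration model parameters
#'
#' The linear model mapping percent C2 volume change to parotid gland
#' migration at the control day:
#' `PGM_c = slope_mm_per_pct * delta_vc2_pct`.
#' The default slope of -0.413 mm per percent is the published
#' calibration against directly measured parotid displacement; with it,
#' contour shrinkage (negative `delta_vc2`) maps to positive (medial)
#' migration. The slope can be overridden to recalibrate.
#'
#' @param slope_mm_per_pct Finite, non-zero slope in mm per percent.
#' @return An object of class `migration_params`.
#' @export
migration_params <- function(slope_mm_per_pct = -0.413) {
  if (!is.finite(slope_mm_per_pct) || slope_mm_per_pct == 0)
    stop("`slope_mm_per_pct` must be finite and non-zero")
  structure(list(slope_mm_per_pct = slope_mm_per_pct),
            class = "migration_params")
}

#' Parotid gland migration at the control day
#'
#' Applies the linear migration model to a percent volume change.
#' Positive values mean migration toward the midline.
#'
#' @param delta_vc2_pct Percent C2 volume change (vectorised).
#' @param params A [migration_params()].
#' @return Migration at the control day in mm.
#' @examples
#' pgm_at_control(1)    # -0.413 mm: contour growth implies lateral motion
#' pgm_at_control(-2)   # +0.826 mm: shrinkage implies medial motion
#' @export
pgm_at_control <- function(delta_vc2_pct, params = migration_params()) {
  stopifnot(inherits(params, "migration_params"))
  if (any(!is.finite(delta_vc2_pct))) stop("`delta_vc2_pct` must be finite")
  params$slope_mm_per_pct * delta_vc2_pct
}

#' Extrapolate migration to the end of treatment
#'
#' Gland migration is approximately linear in time, so the control-day
#' estimate is scaled along the line through the origin at day 0
#' (fraction 1): `PGM = PGM_c * end_day / control_day`.
#'
#' @param pgm_control_mm Migration at the control day in mm (vectorised).
#' @param control_day Days after the first fraction; in (0, end_day].
#' @param end_day Last treatment day.
#' @return Migration at the end of treatment in mm.
#' @export
extrapolate_pgm <- function(pgm_control_mm, control_day, end_day) {
  if (any(!is.finite(pgm_control_mm))) stop("`pgm_control_mm` must be finite")
  if (any(!is.finite(control_day)) || any(!is.finite(end_day)) ||
      any(control_day <= 0) || any(control_day > end_day))
    stop("need 0 < control_day <= end_day")
  pgm_control_mm * end_day / control_day
}

#' Build migration records from serial C2 slab volumes
#'
#' Takes a long table of per-patient C2-level external-contour volumes
#' (one row per acquisition day; a day-0 row is required, the latest
#' later day is used as the control scan) and computes the volume change,
#' the control-day migration, and its linear extrapolation to the end of
#' treatment.
#'
#' @param volumes data.frame with columns `patient_id`, `day`, `vc2_ml`.
#' @param end_day Last treatment day (single value or per-patient,
#'   recycled by patient order).
#' @param params A [migration_params()].
#' @return data.frame with one row per patient: `patient_id`,
#'   `vc2_first_ml`, `vc2_control_ml`, `control_day`, `end_day`,
#'   `delta_vc2_pct`, `pgm_control_mm`, `pgm_mm`.
#' @export
migration_records <- function(volumes, end_day = 40,
                              params = migration_params()) {
  need <- c("patient_id", "day", "vc2_ml")
  if (!is.data.frame(volumes) || !all(need %in% names(volumes)))
    stop("`volumes` must have columns patient_id, day, vc2_ml")
  ids <- unique(volumes$patient_id)
  end_day <- rep_len(end_day, length(ids))
  rows <- lapply(seq_along(ids), function(i) {
    v <- volumes[volumes$patient_id == ids[i], , drop = FALSE]
    if (!any(v$day == 0))
      stop("patient ", ids[i], ": a day-0 (fraction 1) volume is required")
    later <- v[v$day > 0, , drop = FALSE]
    if (nrow(later) == 0L)
      stop("patient ", ids[i], ": no control-day volume after day 0")
    ctrl <- later[which.max(later$day), ]
    v1 <- v$vc2_ml[v$day == 0][1]
    dv <- delta_vc2(v1, ctrl$vc2_ml)
    pgm_c <- pgm_at_control(dv, params)
    data.frame(patient_id = ids[i], vc2_first_ml = v1,
               vc2_control_ml = ctrl$vc2_ml, control_day = ctrl$day,
               end_day = end_day[i], delta_vc2_pct = dv,
               pgm_control_mm = pgm_c,
               pgm_mm = extrapolate_pgm(pgm_c, ctrl$day, end_day[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
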