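# Small in-code fixtures shared across tests.

# dose grid affine along the lateral axis: D = a + b * x (x in mm),
# clipped at 0 so it is a valid dose
ramp_grid <- function(slope, intercept = 0, shape = c(21, 8, 6),
                      spacing = c(1, 2, 2), lateral_axis = 1L) {
  x <- (seq_len(shape[lateral_axis]) - 1) * spacing[lateral_axis]
  prof <- pmax(intercept + slope * x, 0)
  idx <- slice.index(array(0, shape), lateral_axis)
  dose_grid(array(prof[idx], shape), spacing, lateral_axis = lateral_axis)
}

# box mask over inclusive 1-based index ranges
box_mask <- function(shape, from, to, spacing = c(1, 2, 2),
                     lateral_axis = 1L, medial_direction = 1L) {
  a <- array(FALSE, shape)
  a[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  structure_mask(a, spacing, lateral_axis = lateral_axis,
                 medial_direction = medial_direction)
}

# tiny two-class cohort with exact control over features and labels
toy_cohort <- function(md, gradx = NULL, pgm = NULL, label) {
  n <- length(md)
  data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    md_gy = md,
    gradx_gy_per_mm = if (is.null(gradx)) rep(1, n) else gradx,
    pgm_mm = if (is.null(pgm)) rep(0, n) else pgm,
    label = label
  )
}
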