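test_that("mean dose is exact on constant and affine fields", {
  g_const <- ramp_grid(0, intercept = 10)
  m <- box_mask(c(21, 8, 6), c(5, 2, 2), c(15, 6, 5))
  expect_equal(compute_md(g_const, m), 10)

  # D = 0.5 * x: MD equals 0.5 * mean of in-mask voxel-center x, computed
  # by brute force over voxel centers
  g <- ramp_grid(0.5)
  idx <- which(m$values, arr.ind = TRUE)
  x_mm <- (idx[, 1] - 1) * 1
  expect_equal(compute_md(g, m), 0.5 * mean(x_mm), tolerance = 1e-12)
})

test_that("lattice and mask validation errors are raised", {
  g <- ramp_grid(0.5)
  m_other <- box_mask(c(21, 8, 6), c(5, 2, 2), c(15, 6, 5),
                      spacing = c(2, 2, 2))
  expect_error(compute_md(g, m_other), "lattice")
  expect_error(structure_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1)),
               "empty")
  g_small <- dose_grid(array(1, c(2, 4, 4)), c(1, 1, 1))
  m_small <- structure_mask(array(TRUE, c(2, 4, 4)), c(1, 1, 1))
  expect_error(compute_gradx(g_small, m_small), "at least 3 voxels")
})

test_that("GRADX is exact on affine fields with the medial-positive sign", {
  m <- box_mask(c(21, 8, 6), c(5, 2, 2), c(15, 6, 5))
  expect_equal(compute_gradx(ramp_grid(0, intercept = 7), m), 0)
  # ramp rising medially at 1.27 Gy/mm: central differences are exact
  g <- ramp_grid(1.27)
  expect_equal(compute_gradx(g, m), 1.27, tolerance = 1e-12)
  # flipping the medial direction flips the sign
  m_flipped <- box_mask(c(21, 8, 6), c(5, 2, 2), c(15, 6, 5),
                        medial_direction = -1L)
  expect_equal(compute_gradx(g, m_flipped), -1.27, tolerance = 1e-12)
  # the absolute variant ignores the sign convention
  expect_equal(compute_gradx(g, m_flipped, absolute = TRUE), 1.27,
               tolerance = 1e-12)
})

test_that("GRADX equals per-voxel finite-difference enumeration", {
  set.seed(42)
  for (rep in 1:5) {
    shape <- c(sample(3:8, 1), sample(3:6, 1), sample(3:6, 1))
    sp <- runif(3, 0.5, 3)
    vals <- array(runif(prod(shape), 0, 60), shape)
    ax <- sample(1:3, 1)
    g <- dose_grid(vals, sp, lateral_axis = ax)
    mvals <- array(runif(prod(shape)) < 0.4, shape)
    if (!any(mvals)) mvals[1, 1, 1] <- TRUE
    m <- structure_mask(mvals, sp, lateral_axis = ax)

    # oracle: explicit stencil at every voxel
    h <- sp[ax]; n <- shape[ax]
    deriv <- array(NA_real_, shape)
    for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
      for (k in seq_len(shape[3])) {
        idx <- c(i, j, k); p <- idx[ax]
        at <- function(q) { idx2 <- idx; idx2[ax] <- q
          vals[idx2[1], idx2[2], idx2[3]] }
        deriv[i, j, k] <-
          if (p == 1) (at(2) - at(1)) / h
          else if (p == n) (at(n) - at(n - 1)) / h
          else (at(p + 1) - at(p - 1)) / (2 * h)
      }
    expect_equal(compute_gradx(g, m), mean(deriv[mvals]),
                 tolerance = 1e-12)
  }
})

test_that("MD and GRADX are invariant under joint voxel translation", {
  set.seed(7)
  shape <- c(20, 10, 8)
  vals <- array(runif(prod(shape), 0, 50), shape)
  g <- dose_grid(vals, c(1, 2, 2))
  m <- box_mask(shape, c(6, 4, 3), c(10, 7, 6))
  shift <- c(4, 2, 1)
  vals2 <- array(0, shape)
  vals2[(1 + shift[1]):shape[1], (1 + shift[2]):shape[2],
        (1 + shift[3]):shape[3]] <-
    vals[1:(shape[1] - shift[1]), 1:(shape[2] - shift[2]),
         1:(shape[3] - shift[3])]
  g2 <- dose_grid(vals2, c(1, 2, 2))
  m2 <- box_mask(shape, c(6, 4, 3) + shift, c(10, 7, 6) + shift)
  expect_equal(compute_md(g2, m2), compute_md(g, m), tolerance = 1e-12)
  # mask interior keeps clear of the boundary stencils after the shift
  expect_equal(compute_gradx(g2, m2), compute_gradx(g, m),
               tolerance = 1e-12)
})

test_that("delivered mean dose averages planned MD over the course", {
  g <- ramp_grid(0.5, shape = c(30, 8, 6))
  m <- box_mask(c(30, 8, 6), c(5, 2, 2), c(12, 6, 5))
  # identical masks: delivered equals planned
  expect_equal(accumulate_delivered_md(g, list(m, m, m)),
               compute_md(g, m))
  # second mask shifted 2 mm medially on a 0.5 Gy/mm ramp:
  # delivered = planned + slope * 1 mm
  m2 <- box_mask(c(30, 8, 6), c(7, 2, 2), c(14, 6, 5))
  expect_equal(accumulate_delivered_md(g, list(m, m2)),
               compute_md(g, m) + 0.5 * 1, tolerance = 1e-12)
  # uniform dose: motion is invisible
  gu <- ramp_grid(0, intercept = 12, shape = c(30, 8, 6))
  expect_equal(accumulate_delivered_md(gu, list(m, m2)), 12)
  expect_error(accumulate_delivered_md(g, list()), "non-empty")
})

test_that("delivered-dose increment matches the first-order GRADX * PGM / 2 law", {
  # smooth sigmoid phantom, fine lattice, daily linear migration
  spec <- phantom_spec(grid_shape = c(321, 13, 11),
                       spacing_mm = c(0.25, 2, 2),
                       plateau_dose_gy = 40, falloff_center_mm = 44,
                       falloff_scale_mm = 7,
                       gland_center_mm = c(32, 12, 10),
                       gland_radii_mm = c(10, 10, 8))
  d <- make_phantom_dose(spec)
  m <- make_gland_mask(spec)
  planned <- compute_md(d, m)
  gradx <- compute_gradx(d, m)
  # second-order bound constant from the field's second derivative
  h <- spec$spacing_mm[1]
  prof <- d$values[, 1, 1]
  C <- max(abs(diff(prof, differences = 2))) / h^2
  for (pgm in c(1, 2, 3)) {
    traj <- course_trajectory(0:40, pgm / 40)
    delivered <- accumulate_delivered_md(d, simulate_course(m, traj))
    expect_lt(abs((delivered - planned) - gradx * pgm / 2), C * pgm^2)
  }
})
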