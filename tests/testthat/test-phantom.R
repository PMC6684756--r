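test_that("phantom dose follows the logistic falloff along the lateral axis", {
  spec <- phantom_spec(grid_shape = c(41, 11, 9), spacing_mm = c(1, 2, 2),
                       plateau_dose_gy = 40, falloff_center_mm = 20,
                       falloff_scale_mm = 5,
                       gland_center_mm = c(12, 10, 8),
                       gland_radii_mm = c(5, 5, 5))
  d <- make_phantom_dose(spec)
  # sigma(0) = 1/2 at the falloff center (x = 20 mm -> index 21)
  expect_equal(d$values[21, 1, 1], 20)
  # one scale length medial of the center: plateau * sigma(1)
  expect_equal(d$values[26, 1, 1], 40 * plogis(1), tolerance = 1e-12)
  # constant along the non-lateral axes
  expect_equal(max(apply(d$values, 1, function(s) diff(range(s)))), 0)
  # within [0, plateau]
  expect_true(all(d$values >= 0 & d$values <= 40))
})

test_that("an infinitely shallow falloff gives uniform half-plateau dose", {
  spec <- phantom_spec(grid_shape = c(21, 9, 9), spacing_mm = c(1, 1, 1),
                       plateau_dose_gy = 40, falloff_center_mm = 10,
                       falloff_scale_mm = 1e12,
                       gland_center_mm = c(10, 4, 4),
                       gland_radii_mm = c(3, 3, 3))
  d <- make_phantom_dose(spec)
  expect_equal(range(d$values), c(20, 20), tolerance = 1e-9)
})

test_that("phantom spec validation rejects degenerate geometry", {
  expect_error(phantom_spec(grid_shape = c(2, 10, 10)), "grid_shape")
  expect_error(phantom_spec(spacing_mm = c(1, 0, 1)), "spacing")
  expect_error(phantom_spec(falloff_scale_mm = 0), "falloff_scale_mm")
  # gland larger than the grid cannot fit
  expect_error(phantom_spec(gland_radii_mm = c(500, 10, 10)),
               "inside the grid")
})

test_that("gland mask matches brute-force voxel-center enumeration", {
  spec <- phantom_spec(grid_shape = c(21, 21, 21), spacing_mm = c(2, 2, 2),
                       falloff_center_mm = 30, gland_center_mm = c(20, 20, 20),
                       gland_radii_mm = c(10, 10, 10))
  m <- make_gland_mask(spec)
  # independent oracle: loop over all voxel centers
  inside <- 0L
  for (i in 0:20) for (j in 0:20) for (k in 0:20) {
    c_mm <- c(i, j, k) * 2
    if (sum((c_mm - 20)^2) <= 100) inside <- inside + 1L
  }
  expect_identical(sum(m$values), inside)
  # and the in/out status agrees voxel by voxel at a few probes
  expect_true(m$values[11, 11, 11])    # center
  expect_false(m$values[1, 1, 1])
})

test_that("a single-voxel gland at a voxel center gives a 1-voxel mask", {
  spec <- phantom_spec(grid_shape = c(11, 11, 11), spacing_mm = c(2, 2, 2),
                       falloff_center_mm = 10,
                       gland_center_mm = c(10, 10, 10),
                       gland_radii_mm = c(1.9, 1.9, 1.9))
  m <- make_gland_mask(spec)
  expect_identical(sum(m$values), 1L)
  expect_true(m$values[6, 6, 6])
})

test_that("course simulation translates by whole voxels and conserves size", {
  spec <- phantom_spec(grid_shape = c(41, 15, 9), spacing_mm = c(1, 2, 2),
                       falloff_center_mm = 20,
                       gland_center_mm = c(12, 14, 8),
                       gland_radii_mm = c(5, 6, 5))
  m <- make_gland_mask(spec)

  # zero rate: all masks identical
  traj0 <- course_trajectory(c(0, 10, 20), 0)
  masks0 <- simulate_course(m, traj0)
  expect_true(all(vapply(masks0, function(x) identical(x$values, m$values),
                         logical(1))))

  # 0.05 mm/day at day 20 with 1 mm spacing: exactly one voxel medially
  traj <- course_trajectory(c(0, 20), 0.05)
  masks <- simulate_course(m, traj)
  idx0 <- which(masks[[1]]$values, arr.ind = TRUE)
  idx1 <- which(masks[[2]]$values, arr.ind = TRUE)
  expect_equal(sort(idx1[, 1]), sort(idx0[, 1] + 1L))
  # voxel count conserved across fractions
  expect_equal(sum(masks[[2]]$values), sum(masks[[1]]$values))

  # a shift that pushes the gland off the grid errors
  traj_big <- course_trajectory(c(0, 40), 2)
  expect_error(simulate_course(m, traj_big), "leaves the grid")
})

test_that("trajectory validation enforces ordered days starting at 0", {
  expect_error(course_trajectory(c(1, 2), 0.1), "start at 0")
  expect_error(course_trajectory(c(0, 5, 5), 0.1), "strictly increasing")
  tr <- course_trajectory(c(0, 10, 40), 0.05)
  expect_equal(tr$total_shift_mm, 2)
})
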