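test_that("plane through two points is perpendicular to the sagittal plane", {
  p <- plane_through_two_points(c(0, 0, 0), c(10, 0, 0), c(0, 1, 0))
  expect_equal(abs(p$normal), c(0, 0, 1), tolerance = 1e-12)

  # oblique case: normal proportional to (-1, 0, 2)/sqrt(5)
  p2 <- plane_through_two_points(c(0, 0, 0), c(10, 0, 5), c(0, 1, 0))
  expect_equal(abs(p2$normal), c(1, 0, 2) / sqrt(5), tolerance = 1e-12)
  # both defining points satisfy the plane equation
  expect_equal(sum(p2$normal * (c(0, 0, 0) - p2$point)), 0, tolerance = 1e-12)
  expect_equal(sum(p2$normal * (c(10, 0, 5) - p2$point)), 0,
               tolerance = 1e-12)
  # perpendicular to the mid-sagittal plane
  expect_equal(sum(p2$normal * c(0, 1, 0)), 0, tolerance = 1e-12)
  # in-plane axes orthonormal and orthogonal to the normal
  expect_equal(sum(p2$axis1 * p2$axis2), 0, tolerance = 1e-12)
  expect_equal(sum(p2$axis1 * p2$normal), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(p2$axis1^2)), 1, tolerance = 1e-12)

  expect_error(plane_through_two_points(c(1, 2, 3), c(1, 2, 3)), "coincide")
  expect_error(plane_through_two_points(c(0, 0, 0), c(0, 1, 0), c(0, 1, 0)),
               "parallel")
})

test_that("axial plan divides the span into seven slabs, two excluded", {
  lm <- landmark_set(nasal_bone_tip = c(0, 0, 0),
                     atlas_anterior_arch = c(10, 0, 0),
                     nasal_bone_mid = c(5, 0, 7))
  plan <- build_axial_plan(lm)
  expect_equal(length(plan$slabs), 7L)
  expect_equal(plan$excluded_labels, c("X1", "X2"))
  slabs <- analysis_slabs(plan)
  expect_equal(vapply(slabs, `[[`, "", "label"), paste0("A", 1:5))
  expect_equal(plan$thickness_mm, 1.0)
  # A1 spans [2, 3]; its centre plane sits 2.5 mm above the base
  expect_equal(slabs[[1]]$lower_mm, 2)
  expect_equal(slabs[[1]]$upper_mm, 3)
  expect_equal(slabs[[1]]$center$point[3], 2.5, tolerance = 1e-12)
})

test_that("plan slabs tile the extent contiguously with equal thickness", {
  set.seed(42)
  for (i in 1:5) {
    lm <- random_landmark_set()
    plan <- build_axial_plan(lm)
    lows <- vapply(plan$slabs, `[[`, 0, "lower_mm")
    ups <- vapply(plan$slabs, `[[`, 0, "upper_mm")
    expect_equal(lows[1], 0)
    expect_equal(ups[length(ups)], plan$extent_mm, tolerance = 1e-9)
    expect_equal(lows[-1], ups[-length(ups)], tolerance = 1e-9)
    expect_equal(sum(ups - lows), plan$extent_mm, tolerance = 1e-9)
    expect_true(all(abs((ups - lows) - plan$thickness_mm) < 1e-9))
  }
})

test_that("axial plan rejects degenerate landmark configurations", {
  lm <- landmark_set(nasal_bone_tip = c(0, 0, 0),
                     atlas_anterior_arch = c(10, 0, 0),
                     nasal_bone_mid = c(5, 0, 0))  # on the base plane
  expect_error(build_axial_plan(lm), "on or below")
  lm2 <- landmark_set(nasal_bone_tip = c(0, 0, 0),
                      atlas_anterior_arch = c(10, 0, 0))
  expect_error(build_axial_plan(lm2), "nasal_bone_mid")
})

test_that("coronal plan has five equal slabs from anterior plane to joint", {
  lm <- landmark_set(incisor_root = c(0, 0, 0),
                     sagittal_suture = c(10, 0, 0),
                     frontoparietal_joint = c(5, 0, 10))
  plan <- build_coronal_plan(lm)
  expect_equal(length(plan$slabs), 5L)
  expect_equal(plan$excluded_labels, character(0))
  expect_equal(vapply(plan$slabs, `[[`, "", "label"), paste0("C", 1:5))
  expect_equal(plan$thickness_mm, 2)
  expect_equal(plan$slabs[[3]]$center$point[3], 5, tolerance = 1e-12)

  lm_bad <- landmark_set(incisor_root = c(0, 0, 0),
                         sagittal_suture = c(10, 0, 0),
                         frontoparietal_joint = c(5, 0, 0))
  expect_error(build_coronal_plan(lm_bad), "anterior plane")
})

test_that("reslice reproduces an axis-aligned voxel layer exactly", {
  set.seed(3)
  arr <- array(rnorm(21 * 21 * 5, 0, 300), c(21, 21, 5))
  vol <- ct_volume(arr, c(0.1, 0.1, 0.1), origin = c(0, 0, 0))
  k <- 3L  # plane through the voxel centres of layer k (0-based z = 0.2)
  pl <- ct_plane(point = c(1, 1, 0.2), normal = c(0, 0, 1),
                 axis1 = c(1, 0, 0))
  sl <- reslice(vol, pl, 0.1, c(21, 21))
  expect_lt(max(abs(sl$pixels - arr[, , k])), 1e-6)
})

test_that("reslice of a uniform volume is uniform; outside planes are air", {
  vol <- ct_volume(array(50, c(10, 10, 10)), c(0.5, 0.5, 0.5))
  pl <- ct_plane(c(2, 2, 2), normal = c(1, 1, 1))
  sl <- reslice(vol, pl, 0.3, c(9, 9))
  expect_true(all(sl$pixels == -1000 | abs(sl$pixels - 50) < 1e-9))
  expect_equal(sl$pixels[5, 5], 50, tolerance = 1e-9)  # centre well inside

  far <- ct_plane(c(100, 100, 100), normal = c(0, 0, 1))
  sl2 <- reslice(vol, far, 0.3, c(7, 7))
  expect_true(all(sl2$pixels == -1000))
})

test_that("measured index is invariant under joint rigid motion", {
  spec <- phantom_spec(spacing = 0.04)
  ph <- generate_phantom(spec)
  plan <- build_axial_plan(ph$truth$landmarks)
  i0 <- measure_volume(ph$volume, plan, phantom_rois(ph$truth, plan))$value
  set.seed(99)
  for (j in 1:3) {
    rot <- random_rotation()
    tr <- rnorm(3, 0, 2)
    vol2 <- resample_volume(ph$volume, rot, tr)
    lm2 <- transform_landmarks(ph$truth$landmarks, rot, tr)
    plan2 <- build_axial_plan(lm2)
    i1 <- measure_volume(vol2, plan2, phantom_rois(ph$truth, plan2))$value
    expect_lt(abs(i1 - i0), 0.01)
  }
})

test_that("reslice validates its inputs", {
  vol <- ct_volume(array(0, c(4, 4, 4)), c(1, 1, 1))
  pl <- ct_plane(c(0, 0, 0), c(0, 0, 1))
  bad <- pl
  bad$axis2 <- bad$axis1
  expect_error(reslice(vol, bad, 1, c(4, 4)), "orthonormal")
  expect_error(reslice(vol, pl, -1, c(4, 4)), "positive")
})
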