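test_that("ct_volume enforces its invariants", {
  arr <- array(0, c(2, 2, 2))
  expect_s3_class(ct_volume(arr, c(1, 1, 1)), "ct_volume")
  expect_error(ct_volume(array(0, c(0, 2, 2)), c(1, 1, 1)), "zero voxels")
  expect_error(ct_volume(arr, c(1, -1, 1)), "positive")
  expect_error(ct_volume(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)), "finite")
  skew <- diag(3); skew[1, 2] <- 0.2
  expect_error(ct_volume(arr, c(1, 1, 1), orientation = skew), "orthonormal")
})

test_that("DICOM calibration maps stored values through slope/intercept", {
  # stored value 100 with slope 1, intercept -1000 must read back as -900 HU
  dir <- withr::local_tempdir()
  vol <- ct_volume(array(-900, c(4, 4, 1)), c(0.1, 0.1, 0.1))
  write_dicom_series(vol, dir, slope = 1, intercept = -1000)
  el <- rhinoct:::.read_dicom_elements(list.files(dir, full.names = TRUE)[1])
  stored <- readBin(el[["7FE0,0010"]], "integer", n = 16, size = 2,
                    endian = "little")
  expect_true(all(stored == 100))
  back <- load_volume(dir, format = "dicom_series")
  expect_equal(unique(as.numeric(back$voxels)), -900)
})

test_that("HU calibration is affine in slope and intercept", {
  # integer HU so both calibrations represent the values exactly
  base <- array(as.numeric(sample(-500:500, 3 * 3 * 2)), c(3, 3, 2))
  vol <- ct_volume(base, c(0.5, 0.5, 0.5))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dicom_series(vol, d1, slope = 1, intercept = 0)
  write_dicom_series(vol, d2, slope = 0.5, intercept = -250)
  v1 <- load_volume(d1); v2 <- load_volume(d2)
  expect_equal(v2$voxels, v1$voxels, tolerance = 1e-6)
})

test_that("DICOM series round-trips voxels and geometry", {
  set.seed(11)
  vol <- ct_volume(array(sample(-1000:2000, 5 * 6 * 4, TRUE), c(5, 6, 4)),
                   spacing = c(0.02, 0.02, 0.05),
                   origin = c(-3, 1, 2))
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  back <- load_volume(dir)
  expect_equal(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
  expect_equal(back$orientation, vol$orientation, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("mixed-orientation DICOM series is rejected", {
  rot <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  v1 <- ct_volume(array(0, c(4, 4, 2)), c(0.1, 0.1, 0.1))
  v2 <- transform_volume(v1, rotation = rot)
  dir <- withr::local_tempdir()
  write_dicom_series(v1, dir)
  write_dicom_series(v2, file.path(dir, "other"))
  file.copy(file.path(dir, "other", "slice_0001.dcm"),
            file.path(dir, "slice_9999.dcm"))
  unlink(file.path(dir, "other"), recursive = TRUE)
  expect_error(load_volume(dir), "mixed image orientations")
})

test_that("NIfTI round-trip is the identity on voxels and frame", {
  set.seed(7)
  rot <- random_rotation()
  vol <- ct_volume(array(rnorm(4 * 5 * 6, 0, 500), c(4, 5, 6)),
                   spacing = c(0.02, 0.02, 0.05),
                   origin = c(1.5, -2, 0.25),
                   orientation = rot)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  save_volume(vol, path)
  back <- load_volume(path, format = "nifti")
  expect_equal(back$voxels, vol$voxels, tolerance = 1e-5)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-5)
  expect_equal(back$origin, vol$origin, tolerance = 1e-5)
  expect_equal(back$orientation, vol$orientation, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("our NIfTI output agrees with an independent reader", {
  vol <- ct_volume(array(as.numeric(1:24), c(2, 3, 4)),
                   spacing = c(0.5, 0.25, 1), origin = c(-1, 2, 3))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  save_volume(vol, path)
  img <- oro.nifti::readNIfTI(path, reorient = FALSE)
  expect_equal(array(img@.Data, dim = c(2, 3, 4)), vol$voxels,
               tolerance = 1e-6)
  expect_equal(oro.nifti::pixdim(img)[2:4], vol$spacing, tolerance = 1e-6)
})

test_that("degenerate volumes are rejected before writing", {
  expect_error(ct_volume(array(numeric(0), c(0, 0, 0)), c(1, 1, 1)),
               "zero voxels")
  vol <- ct_volume(array(0, c(2, 2, 2)), c(1, 1, 1))
  expect_error(save_volume(vol, "/nonexistent-dir-xyz/v.nii.gz"),
               "directory")
})

test_that("window/level maps endpoints, centre, and clips", {
  expect_equal(render_window_level(matrix(2000 - 5000), 10000, 2000)[1], 0L)
  expect_equal(render_window_level(matrix(2000 + 5000), 10000, 2000)[1],
               255L)
  # the wide CT display window: -3000 HU -> black, +7000 HU -> white
  expect_equal(render_window_level(matrix(-3000))[1], 0L)
  expect_equal(render_window_level(matrix(7000))[1], 255L)
  # window centre rounds half-up: 127.5 -> 128
  expect_equal(render_window_level(matrix(2000))[1], 128L)
  expect_equal(render_window_level(matrix(-1e6))[1], 0L)
  expect_equal(render_window_level(matrix(1e6))[1], 255L)
  expect_error(render_window_level(matrix(0), width = 0), "positive")
})

test_that("window/level is monotone non-decreasing in HU", {
  hu <- sort(runif(200, -4000, 8000))
  g <- render_window_level(matrix(hu, ncol = 1))
  expect_true(all(diff(g) >= 0))
})
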