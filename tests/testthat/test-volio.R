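test_that("NIfTI volume and mask round-trips are exact", {
  cs <- tiny_case(seed = 3)
  td <- withr::local_tempdir()
  vpath <- file.path(td, "vol.nii.gz")
  mpath <- file.path(td, "mask.nii.gz")
  write_volume(cs$volume, vpath)
  write_mask(cs$lung_mask, mpath, reference = cs$volume)
  v2 <- read_volume(vpath)
  m2 <- read_mask(mpath, reference = v2)
  # volumes are written as int16, so compare against the rounded original
  expect_equal(v2$voxels, round(pmin(pmax(cs$volume$voxels, -1024), 3071)),
               ignore_attr = TRUE)
  expect_identical(m2$labels, cs$lung_mask$labels)
  expect_equal(v2$spacing, cs$volume$spacing, tolerance = 1e-6)
  expect_equal(m2$spacing, cs$lung_mask$spacing, tolerance = 1e-6)
})

test_that("volumes stored in a different orientation are normalised on read", {
  arr <- array(rnorm(4 * 5 * 6, -500, 100), c(4, 5, 6)) # nifti (x,y,z)
  img <- RNifti::asNifti(arr)
  RNifti::qform(img) <- structure(rbind(c(2, 0, 0, 0), c(0, 1.5, 0, 0),
                                        c(0, 0, 3, 0), c(0, 0, 0, 1)),
                                  code = 2L) # RAS on disk
  RNifti::pixdim(img) <- c(2, 1.5, 3)
  td <- withr::local_tempdir()
  p <- file.path(td, "ras.nii.gz")
  RNifti::writeNifti(img, p)
  v <- read_volume(p)
  expect_identical(dim(v$voxels), c(6L, 5L, 4L))
  # RAS -> LPS flips x and y; value checks at two corners
  expect_equal(v$voxels[1, 5, 4], arr[1, 1, 1], tolerance = 1e-5)
  expect_equal(v$voxels[6, 1, 1], arr[4, 5, 6], tolerance = 1e-5)
  expect_equal(v$spacing, c(3, 1.5, 2))
})

test_that("mask invariants are enforced", {
  bad <- array(0L, c(16, 32, 32)); bad[1] <- 3L
  expect_error(lung_mask(bad, c(1, 1, 1)), "within \\{0, 1, 2\\}")
  # empty mask is valid and round-trips with zero foreground
  m <- lung_mask(array(0L, c(16, 32, 32)), c(1, 1, 1))
  td <- withr::local_tempdir()
  p <- file.path(td, "empty.nii.gz")
  write_mask(m, p)
  m2 <- read_mask(p)
  expect_identical(sum(m2$labels > 0L), 0L)
  # geometry mismatch against a declared companion volume errors
  v <- ct_volume(array(-1000, c(8, 32, 32)), c(1, 1, 1))
  expect_error(write_mask(m, p, reference = v), "shape")
})

test_that("DICOM slices are rescaled to HU and assembled in z order", {
  td <- withr::local_tempdir()
  set.seed(9)
  stored <- matrix(sample(0:2000, 16 * 16), 16, 16)
  # slope/intercept: stored 0 must become -1024 HU
  for (i in 1:3) {
    write_test_dicom(file.path(td, sprintf("s%d.dcm", i)),
                     stored + i, ipp = c((i - 1) * 2.5, 0, 0),
                     slope = 1, intercept = -1024, pixel_spacing = c(0.7, 0.7))
  }
  v <- read_volume(td)
  expect_identical(dim(v$voxels), c(3L, 16L, 16L))
  expect_equal(v$spacing, c(2.5, 0.7, 0.7))
  expect_equal(v$voxels[1, , ], stored + 1 - 1024, ignore_attr = TRUE)
  expect_equal(v$voxels[3, , ], stored + 3 - 1024, ignore_attr = TRUE)
  expect_equal(min(v$voxels) >= -1024, TRUE)
})

test_that("a DICOM directory mixing two series is rejected", {
  td <- withr::local_tempdir()
  stored <- matrix(0L, 8, 8)
  write_test_dicom(file.path(td, "a.dcm"), stored, ipp = c(0, 0, 0),
                   series_uid = "1.2.3")
  write_test_dicom(file.path(td, "b.dcm"), stored, ipp = c(2, 0, 0),
                   series_uid = "9.8.7")
  expect_error(read_volume(td), "mixes 2 DICOM series")
})

test_that("HU far outside the plausible CT range triggers a warning", {
  arr <- array(0, c(16, 32, 32)); arr[1] <- 5000
  expect_warning(ct_volume(arr, c(1, 1, 1)), "outside the expected")
})
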