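test_that("normalisation maps the HU window endpoints exactly and is monotone", {
  expect_identical(normalize_slice(matrix(-1024)), matrix(0))
  expect_identical(normalize_slice(matrix(600)), matrix(1))
  expect_identical(normalize_slice(matrix(2000)), matrix(1)) # clipped
  expect_identical(normalize_slice(matrix(-2000)), matrix(0))
  hu <- matrix(seq(-1500, 1500, length.out = 101))
  out <- normalize_slice(hu)
  expect_true(all(diff(out) >= 0))
  expect_true(all(out >= 0 & out <= 1))
  # midpoint arithmetic: (v + 1024) / 1624
  expect_equal(normalize_slice(matrix(-212))[1, 1], (-212 + 1024) / 1624)
})

test_that("slice resizing preserves identity, constants, and label sets", {
  img <- matrix(runif(64 * 48), 64, 48)
  expect_equal(resize_slice(img, c(64, 48)), img)
  expect_equal(resize_slice(matrix(0.37, 5, 9), c(256, 256)),
               matrix(0.37, 256, 256))
  lab <- matrix(sample(c(0L, 2L), 4, TRUE), 2, 2)
  up <- resize_slice(lab + 0, c(256, 256), labels = TRUE)
  expect_true(all(up %in% lab))
  expect_error(resize_slice(matrix(numeric(0), 0, 0), c(8, 8)), "non-empty")
})

test_that("body cropping matches a brute-force bounding-box oracle", {
  cs <- tiny_case(seed = 4)
  cr <- crop_to_body(cs$volume)
  # oracle: bbox of >-500 voxels after closing + largest component, +2 margin
  m <- cs$volume$voxels > -500
  m <- thoraxseg:::binary_closing(m, 2)
  m <- thoraxseg:::largest_component(m)
  idx <- which(m, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 2, 1)
  hi <- pmin(apply(idx, 2, max) + 2, dim(cs$volume$voxels))
  expect_identical(cr$transform$lo, as.integer(lo))
  expect_identical(cr$transform$hi, as.integer(hi))
  expect_identical(dim(cr$volume$voxels), as.integer(hi - lo + 1))
})

test_that("cropping handles the degenerate all-air and all-tissue volumes", {
  air <- ct_volume(array(-1000, c(16, 32, 32)), c(1, 1, 1))
  expect_error(crop_to_body(air), "no body found")
  tissue <- ct_volume(array(0, c(16, 32, 32)), c(1, 1, 1))
  cr <- crop_to_body(tissue)
  expect_identical(cr$transform$lo, c(1L, 1L, 1L))
  expect_identical(cr$transform$hi, c(16L, 32L, 32L))
})

test_that("cropping a cropped volume is idempotent up to the margin clip", {
  cs <- tiny_case(seed = 6)
  cr1 <- crop_to_body(cs$volume)
  cr2 <- crop_to_body(cr1$volume)
  d1 <- dim(cr1$volume$voxels)
  # the second crop can only trim the (air-filled) margin, never more
  expect_true(all(cr2$transform$lo <= 3L))
  expect_true(all(d1 - cr2$transform$hi <= 2L))
})

test_that("forward preprocessing then backprojection round-trips the mask", {
  for (seed in c(1, 9)) {
    cs <- tiny_case(seed = seed)
    pp <- preprocess_volume(cs$volume, target_size = c(128, 128))
    stack <- thoraxseg:::forward_mask_slices(cs$lung_mask, pp$transform)
    back <- backproject_mask(stack, pp$transform, cs$volume)
    expect_gte(dsc(back$labels == 1L, cs$lung_mask$labels == 1L), 0.99)
    expect_gte(dsc(back$labels == 2L, cs$lung_mask$labels == 2L), 0.99)
  }
})

test_that("backprojection zero-fills outside the crop and validates inputs", {
  cs <- tiny_case(seed = 2)
  pp <- preprocess_volume(cs$volume, target_size = c(64, 64))
  nz <- dim(pp$images)[3]
  zero <- array(0L, c(64, 64, nz))
  back <- backproject_mask(zero, pp$transform, cs$volume)
  expect_identical(sum(back$labels), 0L)
  ones <- array(1L, c(64, 64, nz))
  back1 <- backproject_mask(ones, pp$transform, cs$volume)
  tf <- pp$transform
  outside <- array(TRUE, dim(cs$volume$voxels))
  outside[tf$lo[1]:tf$hi[1], tf$lo[2]:tf$hi[2], tf$lo[3]:tf$hi[3]] <- FALSE
  expect_identical(sum(back1$labels[outside]), 0L)
  # mismatched reference is refused
  other <- ct_volume(array(0, dim(cs$volume$voxels) + c(1L, 0L, 0L)), cs$volume$spacing)
  expect_error(backproject_mask(zero, pp$transform, other), "does not match")
  expect_error(backproject_mask(zero[, , -1], pp$transform, cs$volume), "depth")
})
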