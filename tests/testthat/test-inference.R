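test_that("dense-area removal applies the strict HU window and never adds voxels", {
  d <- c(16L, 32L, 32L)
  vox <- array(-800, d)
  vox[8, 10, 10] <- 0      # inside (-50, 70): must go
  vox[8, 10, 11] <- -500   # outside: stays
  vox[8, 10, 12] <- 70     # boundary: strict inequality, stays
  vox[8, 10, 13] <- -50    # boundary: stays
  vol <- ct_volume(vox, c(1, 1, 1))
  lab <- array(0L, d); lab[6:10, 8:14, 8:16] <- 1L
  mask <- lung_mask(lab, c(1, 1, 1))
  out <- remove_dense_areas(mask, vol)
  expect_identical(out$labels[8, 10, 10], 0L)
  expect_identical(out$labels[8, 10, 11], 1L)
  expect_identical(out$labels[8, 10, 12], 1L)
  expect_identical(out$labels[8, 10, 13], 1L)
  expect_true(all(out$labels[mask$labels == 0L] == 0L)) # subset invariant
  other <- ct_volume(array(0, d + c(1L, 0L, 0L)), c(1, 1, 1))
  expect_error(remove_dense_areas(mask, other), "shape")
})

test_that("relabelling assigns sides by position and preserves empty masks", {
  d <- c(16L, 32L, 48L)
  lab <- array(0L, d)
  lab[6:10, 10:20, 5:15] <- 1L    # low x: right
  lab[6:10, 10:20, 30:40] <- 1L   # high x: must become left
  m <- relabel_left_right(lung_mask(lab, c(1, 1, 1)))
  expect_identical(unique(as.vector(m$labels[, , 5:15])), c(0L, 1L))
  expect_identical(unique(as.vector(m$labels[, , 30:40])), c(0L, 2L))
  empty <- lung_mask(array(0L, d), c(1, 1, 1))
  expect_identical(relabel_left_right(empty)$labels, empty$labels)
})

test_that("a fused component is split at the midline with voxel conservation", {
  d <- c(16L, 32L, 48L)
  lab <- array(0L, d)
  lab[6:10, 10:20, 5:43] <- 1L    # one component spanning the midline
  n_before <- sum(lab > 0L)
  m <- relabel_left_right(lung_mask(lab, c(1, 1, 1)))
  expect_identical(sum(m$labels > 0L), n_before)
  expect_gt(sum(m$labels == 1L), 0L)
  expect_gt(sum(m$labels == 2L), 0L)
  # right voxels all at lower x than left voxels
  xr <- which(apply(m$labels == 1L, 3, any))
  xl <- which(apply(m$labels == 2L, 3, any))
  expect_lt(max(xr), min(xl))
})

test_that("mixed labels within a component are made consistent", {
  d <- c(16L, 32L, 48L)
  lab <- array(0L, d)
  lab[6:10, 10:20, 5:15] <- 1L
  lab[8, 15, 10] <- 2L # a few mislabelled voxels inside the right component
  lab[9, 15, 10] <- 2L
  lab[6:10, 10:20, 30:40] <- 2L
  m <- relabel_left_right(lung_mask(lab, c(1, 1, 1)))
  expect_identical(unique(as.vector(m$labels[, , 5:15][m$labels[, , 5:15] > 0L])), 1L)
  # a degenerate labelling (both lungs emitted as one class) is repaired
  lab2 <- array(0L, d)
  lab2[6:10, 10:20, 5:15] <- 1L
  lab2[6:10, 10:20, 30:40] <- 1L
  m2 <- relabel_left_right(lung_mask(lab2, c(1, 1, 1)))
  expect_identical(unique(as.vector(m2$labels[, , 30:40][m2$labels[, , 30:40] > 0L])), 2L)
  expect_gt(sum(m2$labels == 1L), 0L)
})

test_that("segmenting a phantom returns the input geometry and finds the lungs", {
  model <- trained_tiny_model()
  cs <- tiny_case(seed = 101)
  pred <- segment_volume(model, cs$volume, target_size = c(48L, 48L))
  expect_identical(dim(pred$labels), dim(cs$volume$voxels))
  expect_equal(pred$spacing, cs$volume$spacing)
  ev <- evaluate_case(pred, cs$lung_mask)
  expect_gt(ev$dsc[ev$label == "mean"], 0.85)
  # determinism for a fixed checkpoint
  pred2 <- segment_volume(model, cs$volume, target_size = c(48L, 48L))
  expect_identical(pred$labels, pred2$labels)
})

test_that("a volume of pure air fails with the crop-stage error", {
  model <- trained_tiny_model()
  air <- ct_volume(array(-1000, c(16, 48, 48)), c(5, 2, 2))
  expect_error(segment_volume(model, air), "no body found")
})

test_that("pure-air slices contribute no foreground to a volume segmentation", {
  # air-only slices fall outside the body crop, so the pipeline guarantees
  # they come back all-background regardless of the raw model's behaviour
  model <- trained_tiny_model()
  cs <- tiny_case(seed = 131)
  padded <- cs$volume$voxels
  padded[c(1L, dim(padded)[1]), , ] <- -1000 # cranial/caudal air-only slices
  vol <- ct_volume(padded, cs$volume$spacing, id = "padded")
  pred <- segment_volume(model, vol, target_size = c(48L, 48L))
  expect_identical(sum(pred$labels[c(1L, dim(padded)[1]), , ]), 0L)
})
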