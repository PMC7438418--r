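test_that("phantom generation is deterministic and labels are consistent", {
  spec <- tiny_spec()
  a <- generate_phantom(spec, 7)
  b <- generate_phantom(spec, 7)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$lung_mask$labels, b$lung_mask$labels)
  expect_identical(a$pathology_map, b$pathology_map)
  expect_true(all(a$lung_mask$labels %in% 0:2))
  # right/left components are disjoint by construction of the label array;
  # check they are also spatially separated (no 6-adjacency)
  r <- a$lung_mask$labels == 1L
  l <- a$lung_mask$labels == 2L
  expect_false(any(thoraxseg:::binary_dilate(r, 1) & l))
})

test_that("right lung (label 1) sits at lower x than left (label 2)", {
  cs <- tiny_case(seed = 2)
  xr <- which(apply(cs$lung_mask$labels == 1L, 3, any))
  xl <- which(apply(cs$lung_mask$labels == 2L, 3, any))
  expect_lt(mean(xr), mean(xl))
})

test_that("pathology-free spec yields an all-zero pathology map", {
  cs <- tiny_case(seed = 7, pathology = "none")
  expect_identical(unique(as.vector(cs$pathology_map)), 0L)
})

test_that("a tumour case has exactly one 6-connected component inside the lung", {
  cs <- tiny_case(seed = 1, pathology = "tumour")
  tm <- cs$pathology_map == 3L
  expect_gt(sum(tm), 0)
  lab <- thoraxseg:::label_components(tm)
  expect_identical(max(lab), 1L)
  expect_true(all(cs$lung_mask$labels[tm] > 0L))
})

test_that("dense pathologies lie inside the lung mask; pneumothorax is air", {
  for (pat in c("effusion", "consolidation", "tumour")) {
    cs <- tiny_case(seed = 11, pathology = pat)
    sel <- cs$pathology_map %in% 1:3
    expect_gt(sum(sel), 0)
    expect_true(all(cs$lung_mask$labels[sel] > 0L))
  }
  cs <- tiny_case(seed = 11, pathology = "pneumothorax")
  px <- cs$pathology_map == 4L
  expect_gt(sum(px), 0)
  expect_true(all(cs$volume$voxels[px] < -900))
  expect_true(all(cs$lung_mask$labels[px] == 0L))
})

test_that("each lung volume is an anatomically plausible fraction of the body", {
  for (seed in c(3, 14, 25)) {
    cs <- tiny_case(seed = seed)
    body <- sum(cs$volume$voxels > -500) +
      sum(cs$lung_mask$labels > 0L & cs$volume$voxels <= -500)
    for (lv in 1:2) {
      frac <- sum(cs$lung_mask$labels == lv) / body
      expect_gt(frac, 0.02)
      expect_lt(frac, 0.40)
    }
  }
})

test_that("some cranial/caudal slices contain no lung", {
  cs <- tiny_case(seed = 5)
  lung_per_slice <- apply(cs$lung_mask$labels > 0L, 1, any)
  expect_true(any(!lung_per_slice))
  expect_true(any(lung_per_slice))
})

test_that("cohort seeds derive from the master seed and are reproducible", {
  spec <- tiny_spec()
  co1 <- generate_cohort(spec, 3, seed = 5)
  co2 <- generate_cohort(spec, 3, seed = 5)
  expect_identical(co1[[2]]$volume$voxels, co2[[2]]$volume$voxels)
  # n = 1 equals generate_phantom on the derived seed
  one <- generate_cohort(spec, 1, seed = 5)
  derived <- thoraxseg:::derive_seeds(5, 1)
  expect_identical(one[[1]]$volume$voxels,
                   generate_phantom(spec, derived)$volume$voxels)
})

test_that("empirical pathology frequencies follow the requested mix", {
  spec <- tiny_spec(pathology_mix = c(effusion = 0.5, none = 0.5))
  cohort <- generate_cohort(spec, 200, seed = 3)
  k <- sum(vapply(cohort, `[[`, "", "pathology") == "effusion")
  ci <- qbinom(c(0.005, 0.995), 200, 0.5) # central 99% binomial interval
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(shape = c(8, 32, 32)), "z >= 16")
  expect_error(phantom_spec(pathology_mix = c(tumour = 1.2)), "\\[0, 1\\]")
  expect_error(phantom_spec(pathology_mix = c(fibrosis = 1)), "names")
  expect_error(phantom_spec(spacing = c(0, 1, 1)), "positive")
})

test_that("cohorts round-trip through the on-disk NIfTI + manifest layout", {
  td <- withr::local_tempdir()
  spec <- tiny_spec(pathology_mix = c(tumour = 1))
  cases <- generate_cohort(spec, 2, seed = 8)
  manifest <- write_cohort(cases, td)
  expect_identical(nrow(manifest), 2L)
  expect_true(all(manifest$pathology == "tumour"))
  expect_true(file.exists(file.path(td, "manifest.csv")))
  v <- read_volume(file.path(td, paste0(manifest$case[1], "_ct.nii.gz")))
  m <- read_mask(file.path(td, paste0(manifest$case[1], "_mask.nii.gz")),
                 reference = v)
  expect_identical(m$labels, cases[[1]]$lung_mask$labels)
})
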