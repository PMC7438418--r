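make_records <- function(n_lung, n_bg, h = 16L) {
  img <- matrix(0.5, h, h)
  lab_fg <- matrix(0L, h, h); lab_fg[5:8, 5:8] <- 1L
  lab_bg <- matrix(0L, h, h)
  tibble::tibble(
    image = c(replicate(n_lung, img, simplify = FALSE),
              replicate(n_bg, img, simplify = FALSE)),
    label = c(replicate(n_lung, lab_fg, simplify = FALSE),
              replicate(n_bg, lab_bg, simplify = FALSE)),
    has_lung = rep(c(TRUE, FALSE), c(n_lung, n_bg)),
    case_id = "c"
  )
}

test_that("every stratified batch holds exactly 7 lung and 7 non-lung slices", {
  rec <- make_records(100, 100)
  cfg <- train_config()
  withr::with_seed(1, {
    batches <- stratified_batches(rec$has_lung, cfg)
    for (b in batches) {
      expect_length(b, 14L)
      expect_identical(sum(rec$has_lung[b]), 7L)
    }
  })
})

test_that("a scarce stratum is resampled with replacement to fill batches", {
  rec <- make_records(7, 700)
  withr::with_seed(2, {
    batches <- stratified_batches(rec$has_lung, train_config())
    expect_gte(length(batches), 100) # majority stratum covered once
    for (b in head(batches, 20)) {
      expect_identical(sum(rec$has_lung[b]), 7L)
    }
    # the 7 lung slices must repeat across batches
    lung_draws <- unlist(lapply(batches, function(b) b[rec$has_lung[b]]))
    expect_gt(max(table(lung_draws)), 1)
  })
})

test_that("an empty stratum is reported by name", {
  rec <- make_records(5, 0)
  expect_error(withr::with_seed(1, stratified_batches(rec$has_lung, train_config())),
               "non-lung")
  rec2 <- make_records(0, 5)
  expect_error(withr::with_seed(1, stratified_batches(rec2$has_lung, train_config())),
               "'lung'")
})

test_that("batch order is a seeded permutation: reproducible, seed-sensitive", {
  rec <- make_records(50, 50)
  b1 <- withr::with_seed(3, stratified_batches(rec$has_lung, train_config()))
  b2 <- withr::with_seed(3, stratified_batches(rec$has_lung, train_config()))
  b3 <- withr::with_seed(4, stratified_batches(rec$has_lung, train_config()))
  expect_identical(b1, b2)
  expect_false(identical(b1, b3))
})

test_that("augmentation at zero amplitude is the identity", {
  img <- matrix(runif(64 * 64), 64, 64)
  lab <- matrix(sample(0:2, 64 * 64, TRUE), 64, 64)
  out <- withr::with_seed(1, augment_slice(img, lab,
    aug = list(rot_deg_max = 0, deform_grid = 4, deform_sigma_px = 0, noise_sigma = 0)))
  expect_identical(out$image, img)
  expect_identical(out$label, lab)
})

test_that("augmentation preserves the label set and is seed-deterministic", {
  img <- matrix(runif(64 * 64), 64, 64)
  lab <- matrix(0L, 64, 64); lab[10:30, 40:60] <- 2L
  aug <- list(rot_deg_max = 10, deform_grid = 4, deform_sigma_px = 2,
              noise_sigma = 0.02)
  a1 <- withr::with_seed(5, augment_slice(img, lab, aug))
  a2 <- withr::with_seed(5, augment_slice(img, lab, aug))
  expect_identical(a1$image, a2$image)
  expect_identical(a1$label, a2$label)
  expect_true(all(a1$label %in% c(0L, 2L)))
})

test_that("image and label stay aligned under the same warp", {
  # warping a mask as image (bilinear of 0/1) thresholded at 0.5 must agree
  # with the label path almost everywhere off the boundary
  m <- matrix(0L, 64, 64); m[20:40, 20:40] <- 1L
  aug <- list(rot_deg_max = 10, deform_grid = 4, deform_sigma_px = 2, noise_sigma = 0)
  out <- withr::with_seed(8, augment_slice(m + 0, m, aug))
  img_bin <- out$image > 0.5
  agree <- mean(img_bin == (out$label > 0L))
  expect_gt(agree, 0.99)
})

test_that("a short training run descends and is reproducible under a seed", {
  spec <- tiny_spec(pathology_mix = c(none = 1))
  cases <- generate_cohort(spec, 4, seed = 31)
  rec <- slice_records(cases, target_size = c(32L, 32L))
  run <- function() {
    m <- withr::with_seed(9, build_model(net_config(base_width = 4, depth = 2)))
    m <- train_model(m, rec, train_config(epochs = 3, seed = 9, val_fraction = 0))
    tidy(m)
  }
  h1 <- run()
  expect_lt(h1$loss[3], h1$loss[1])
  h2 <- run()
  expect_identical(h1$loss, h2$loss) # deterministic training curves
})

test_that("training aborts with a diagnostic when the loss diverges", {
  rec <- make_records(10, 10, h = 16L)
  m <- withr::with_seed(10, build_model(net_config(base_width = 4, depth = 2)))
  expect_error(
    train_model(m, rec, train_config(epochs = 2, seed = 1, lr = 1e6, val_fraction = 0)),
    "diverged"
  )
})
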