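test_that("dsc follows set arithmetic, symmetry, and the empty-mask rules", {
  d <- c(10L, 10L, 10L)
  x <- array(FALSE, d); y <- array(FALSE, d)
  x[1:4, 1:5, 1:5] <- TRUE            # |X| = 100
  y[3:6, 1:5, 1:5] <- TRUE            # |Y| = 100, |X ∩ Y| = 50
  expect_identical(dsc(x, y), 0.5)
  expect_identical(dsc(x, y), dsc(y, x))
  expect_identical(dsc(x, x), 1)
  z <- array(FALSE, d); z[10, 10, 10] <- TRUE
  expect_identical(dsc(x, z), 0)      # disjoint, both non-empty
  e <- array(FALSE, d)
  expect_identical(dsc(e, e), 1)      # empty vs empty: perfect agreement
  expect_identical(dsc(e, x), 0)
  expect_error(dsc(x, array(FALSE, c(9, 10, 10))), "same shape")
})

test_that("dsc never decreases when true positives grow at fixed mask sizes", {
  withr::with_seed(1, {
    for (i in 1:20) {
      x <- random_mask(); y <- random_mask()
      base <- dsc(x, y)
      # move one foreground voxel of y from outside X to inside X
      wrong <- which(y & !x); right <- which(x & !y)
      if (length(wrong) > 0 && length(right) > 0) {
        y2 <- y; y2[wrong[1]] <- FALSE; y2[right[1]] <- TRUE
        expect_gte(dsc(x, y2), base)
      }
    }
  })
})

test_that("single-voxel masks k voxels apart give HD95 = MSD = k * spacing", {
  d <- c(12L, 12L, 12L)
  x <- array(FALSE, d); y <- array(FALSE, d)
  x[2, 5, 5] <- TRUE
  y[5, 5, 5] <- TRUE                   # 3 voxels apart along z
  sp <- c(2, 1, 1)
  expect_equal(hd95(x, y, sp), 6.0)
  expect_equal(msd(x, y, sp), 6.0)
  # 5 mm apart along y with unit spacing
  y2 <- array(FALSE, d); y2[2, 10, 5] <- TRUE
  expect_equal(hd95(x, y2, c(1, 1, 1)), 5.0)
  expect_equal(msd(x, y2, c(1, 1, 1)), 5.0)
  # identical masks: all metrics vanish
  expect_equal(hd95(x, x, sp), 0.0)
  expect_equal(msd(x, x, sp), 0.0)
  expect_identical(dsc(x, x), 1)
})

test_that("surface metrics match the brute-force all-pairs oracle", {
  withr::with_seed(42, {
    for (i in 1:25) {
      sp <- runif(3, 0.5, 4)
      x <- random_mask(); y <- random_mask()
      expect_equal(hd95(x, y, sp), oracle_hd95(x, y, sp), tolerance = 1e-9)
      expect_equal(msd(x, y, sp), oracle_msd(x, y, sp), tolerance = 1e-9)
    }
  })
})

test_that("surface metrics are translation invariant and scale with spacing", {
  withr::with_seed(7, {
    x <- array(FALSE, c(24, 24, 24)); y <- array(FALSE, c(24, 24, 24))
    x[4:9, 4:9, 4:9] <- TRUE
    y[6:12, 5:8, 7:11] <- TRUE
    sp <- c(1.5, 1, 2)
    h0 <- hd95(x, y, sp); m0 <- msd(x, y, sp)
    shift <- function(m, k) {
      out <- array(FALSE, dim(m))
      out[(1 + k):dim(m)[1], , ] <- m[1:(dim(m)[1] - k), , ]
      out
    }
    expect_equal(hd95(shift(x, 5), shift(y, 5), sp), h0, tolerance = 1e-12)
    expect_equal(msd(shift(x, 5), shift(y, 5), sp), m0, tolerance = 1e-12)
    expect_equal(hd95(x, y, 3 * sp), 3 * h0, tolerance = 1e-12)
    expect_equal(msd(x, y, 3 * sp), 3 * m0, tolerance = 1e-12)
  })
})

test_that("empty masks make surface distances undefined", {
  x <- array(FALSE, c(8, 8, 8)); y <- x; y[4, 4, 4] <- TRUE
  expect_error(hd95(x, y, c(1, 1, 1)), "undefined surface distance")
  expect_error(msd(y, x, c(1, 1, 1)), "undefined surface distance")
})

test_that("the msd convention switch averages instead of taking the max", {
  withr::with_seed(3, {
    x <- random_mask(); y <- random_mask()
    d <- oracle_surface_distances(x, y, c(1, 1, 1))
    expect_equal(msd(x, y, c(1, 1, 1), convention = "mean"),
                 (mean(d$dxy) + mean(d$dyx)) / 2, tolerance = 1e-9)
  })
})

test_that("tumour overlap is the covered fraction of tumour volume", {
  d <- c(10L, 10L, 10L)
  lung <- array(FALSE, d); lung[, , 1:5] <- TRUE
  tum <- array(FALSE, d); tum[1:2, 1:10, 1:10] <- TRUE # 200 voxels, 100 inside
  expect_equal(tumour_overlap(lung, tum), 0.5)
  tin <- array(FALSE, d); tin[1, 1, 1:3] <- TRUE
  expect_identical(tumour_overlap(lung, tin), 1)
  tout <- array(FALSE, d); tout[1, 1, 6:9] <- TRUE
  expect_identical(tumour_overlap(lung, tout), 0)
  expect_error(tumour_overlap(lung, array(FALSE, d)), "empty")
})

test_that("paired t-test matches the closed form and flags degenerate pairs", {
  # differences (1, 2, 3): t = mean/ (sd/sqrt(n)) = 2 / (1/sqrt(3))
  a <- c(2, 4, 6); b <- c(1, 2, 3)
  res <- paired_t(a, b)
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * stats::pt(-res$t, df = 2), tolerance = 1e-9)
  # antisymmetry
  res2 <- paired_t(b, a)
  expect_equal(res2$t, -res$t)
  expect_equal(res2$p, res$p)
  expect_error(paired_t(a, a), "degenerate")
  expect_error(paired_t(1, 2), "length")
})

test_that("per-case evaluation averages the two lungs and handles edge cases", {
  cs <- tiny_case(seed = 8)
  gt <- cs$lung_mask
  ev <- evaluate_case(gt, gt)
  expect_identical(ev$dsc, c(1, 1, 1))
  expect_equal(ev$hd95_mm, c(0, 0, 0))
  expect_equal(ev$msd_mm, c(0, 0, 0))
  expect_identical(ev$label, c("right", "left", "mean"))
  # empty prediction: dsc 0, undefined distances flagged as NA
  empty <- lung_mask(array(0L, dim(gt$labels)), gt$spacing)
  ev0 <- suppressWarnings(evaluate_case(empty, gt))
  expect_identical(ev0$dsc[ev0$label == "mean"], 0)
  expect_true(all(is.na(ev0$hd95_mm)))
  # a lung label missing from the ground truth is skipped with a warning
  gt_right <- lung_mask(ifelse(gt$labels == 2L, 0L, gt$labels), gt$spacing)
  expect_warning(ev1 <- evaluate_case(gt_right, gt_right), "skipped")
  expect_identical(ev1$label, c("right", "mean"))
})

test_that("whole-lung mode ignores the left/right split", {
  cs <- tiny_case(seed = 12)
  gt <- cs$lung_mask
  swapped <- gt
  swapped$labels <- ifelse(gt$labels == 1L, 2L,
                           ifelse(gt$labels == 2L, 1L, 0L))
  ev_whole <- evaluate_case(swapped, gt, mode = "whole")
  expect_identical(ev_whole$dsc, 1)
  ev_per <- evaluate_case(swapped, gt)
  expect_identical(ev_per$dsc[ev_per$label == "mean"], 0)
})

test_that("cohort summaries aggregate means, SDs and undefined counts", {
  report <- tibble::tibble(
    case = c("a", "b", "c"), label = "mean",
    dsc = c(0.90, 0.96, 0), hd95_mm = c(2, 4, NA), msd_mm = c(1, 3, NA)
  )
  s <- summarize_metrics(report)
  expect_equal(s$dsc_mean, mean(c(0.9, 0.96, 0)))
  expect_equal(s$hd95_mean, 3)
  expect_identical(s$n_undefined, 1L)
})
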