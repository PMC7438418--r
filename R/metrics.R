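#' Dice similarity coefficient
#'
#' Overlap between two binary masks: `2|X ∩ Y| / (|X| + |Y|)`. Two empty
#' masks agree perfectly and score 1; an empty mask against a non-empty one
#' scores 0.
#'
#' @param x,y binary (logical or 0/1) arrays of identical shape.
#' @return A number in \[0, 1\].
#' @export
dsc <- function(x, y) {
  assert_that(identical(dim(x), dim(y)), "masks must have the same shape")
  sx <- sum(x != 0); sy <- sum(y != 0)
  if (sx + sy == 0) return(1)
  2 * sum(x != 0 & y != 0) / (sx + sy)
}

# directed nearest-surface distances (mm) from every surface voxel of `from`
# to the surface of `to`, via the exact anisotropic distance transform
directed_surface_distances <- function(from, to, spacing) {
  sf <- surface_voxels(from)
  st <- surface_voxels(to)
  if (!any(sf) || !any(st)) abort("undefined surface distance: empty mask")
  d2 <- .cpp_edt3d(st, dim(to)[1], dim(to)[2], dim(to)[3], as.numeric(spacing))
  sqrt(d2[sf])
}

#' Robust (95th percentile) Hausdorff distance
#'
#' Surfaces are the 6-neighbourhood border voxels of each mask; distances
#' are Euclidean between voxel centres, in mm, aware of anisotropic
#' spacing. Each directed value is the 95th percentile (linear
#' interpolation between order statistics) of the nearest-surface
#' distances; the symmetric value is the maximum of the two directions.
#'
#' @param x,y non-empty binary arrays of identical shape.
#' @param spacing numeric length-3 voxel spacing in mm `(z, y, x)`.
#' @param percentile percentile of the distance distribution (default 95).
#' @return Distance in mm.
#' @export
hd95 <- function(x, y, spacing, percentile = 95) {
  assert_that(identical(dim(x), dim(y)), "masks must have the same shape")
  dxy <- directed_surface_distances(x, y, spacing)
  dyx <- directed_surface_distances(y, x, spacing)
  max(quantile(dxy, percentile / 100, names = FALSE, type = 7),
      quantile(dyx, percentile / 100, names = FALSE, type = 7))
}

#' Mean surface distance
#'
#' Directed value: mean nearest-surface distance from one surface to the
#' other. The symmetric form used by default takes the maximum of the two
#' directed means; `convention = "mean"` averages them instead (the more
#' common convention in the literature; see the methods vignette for why
#' both exist).
#'
#' @inheritParams hd95
#' @param convention `"max"` (default) or `"mean"` for symmetrisation.
#' @return Distance in mm.
#' @export
msd <- function(x, y, spacing, convention = c("max", "mean")) {
  convention <- match.arg(convention)
  assert_that(identical(dim(x), dim(y)), "masks must have the same shape")
  dxy <- mean(directed_surface_distances(x, y, spacing))
  dyx <- mean(directed_surface_distances(y, x, spacing))
  if (convention == "max") max(dxy, dyx) else (dxy + dyx) / 2
}

#' Proportion of tumour volume covered by a lung mask
#'
#' @param lung binary (or labelled) lung mask array.
#' @param tumour non-empty binary tumour mask array of the same shape.
#' @return `|tumour ∩ lung| / |tumour|` in \[0, 1\].
#' @export
tumour_overlap <- function(lung, tumour) {
  assert_that(identical(dim(lung), dim(tumour)), "masks must have the same shape")
  nt <- sum(tumour != 0)
  assert_that(nt > 0, "tumour mask is empty")
  sum(tumour != 0 & lung != 0) / nt
}

#' Paired t-test on per-case metric values
#'
#' Classical two-sided paired t-test on the per-case differences, as used to
#' compare segmentation results between training cohorts.
#'
#' @param a,b numeric vectors of equal length (>= 2), paired by case.
#' @return A tibble with `t`, `df`, `p`, and `mean_diff`.
#' @export
paired_t <- function(a, b) {
  assert_that(length(a) == length(b) && length(a) >= 2,
              "paired vectors must have equal length >= 2")
  d <- a - b
  if (sd(d) == 0) abort("degenerate pairs: differences have zero variance")
  tt <- t.test(a, b, paired = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_diff = mean(d))
}

lung_label_names <- c(`1` = "right", `2` = "left")

#' Evaluate a predicted mask against ground truth
#'
#' Computes DSC, HD95 and MSD per lung (right = label 1, left = label 2)
#' and their across-lung arithmetic mean, on the 3-D volumes. A lung label
#' empty in the ground truth is skipped with a warning; an empty prediction
#' against a non-empty ground truth scores DSC 0 with undefined (NA)
#' surface distances. `mode = "whole"` merges both lungs into a single
#' foreground label before comparison, for methods that do not separate
#' left and right.
#'
#' @param pred,gt [lung_mask()] objects on the same grid.
#' @param mode `"per_lung"` (default) or `"whole"`.
#' @param msd_convention passed to [msd()].
#' @return A tibble with columns `case`, `label`, `dsc`, `hd95_mm`,
#'   `msd_mm`; `label` is `"right"`, `"left"` and `"mean"` (or `"whole"`).
#' @export
evaluate_case <- function(pred, gt, mode = c("per_lung", "whole"),
                          msd_convention = "max") {
  mode <- match.arg(mode)
  check_same_geometry(pred, gt, "prediction and ground truth")
  spacing <- gt$spacing
  one <- function(pm, gm, label) {
    if (!any(gm)) {
      warn(sprintf("ground truth has no '%s' voxels; lung skipped", label))
      return(NULL)
    }
    if (!any(pm)) {
      return(tibble(case = gt$id, label = label, dsc = 0,
                    hd95_mm = NA_real_, msd_mm = NA_real_))
    }
    tibble(case = gt$id, label = label, dsc = dsc(pm, gm),
           hd95_mm = hd95(pm, gm, spacing),
           msd_mm = msd(pm, gm, spacing, convention = msd_convention))
  }
  if (mode == "whole") {
    return(one(pred$labels > 0L, gt$labels > 0L, "whole"))
  }
  rows <- dplyr::bind_rows(
    one(pred$labels == 1L, gt$labels == 1L, "right"),
    one(pred$labels == 2L, gt$labels == 2L, "left")
  )
  if (nrow(rows) == 0) return(rows)
  avg <- tibble(case = gt$id, label = "mean",
                dsc = mean(rows$dsc),
                hd95_mm = mean(rows$hd95_mm),
                msd_mm = mean(rows$msd_mm))
  dplyr::bind_rows(rows, avg)
}

#' Evaluate predictions for a whole cohort
#'
#' @param preds,gts lists of [lung_mask()] objects, paired by position.
#' @param ... passed to [evaluate_case()].
#' @return A tibble of per-case rows (see [evaluate_case()]).
#' @export
evaluate_cohort <- function(preds, gts, ...) {
  assert_that(length(preds) == length(gts), "preds and gts must pair up")
  dplyr::bind_rows(purrr::map2(preds, gts, evaluate_case, ...))
}

#' Aggregate a metrics table
#'
#' Mean and standard deviation over cases, per label. Undefined (NA)
#' surface distances — from empty predictions — are excluded from the
#' aggregates and counted in `n_undefined`.
#'
#' @param report tibble from [evaluate_cohort()].
#' @return A tibble with one row per label.
#' @export
summarize_metrics <- function(report) {
  report |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      dsc_mean = mean(.data$dsc), dsc_sd = sd(.data$dsc),
      hd95_mean = mean(.data$hd95_mm, na.rm = TRUE),
      hd95_sd = sd(.data$hd95_mm, na.rm = TRUE),
      msd_mean = mean(.data$msd_mm, na.rm = TRUE),
      msd_sd = sd(.data$msd_mm, na.rm = TRUE),
      n_undefined = sum(is.na(.data$hd95_mm)),
      .groups = "drop"
    )
}
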