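#' Segment a CT volume slice by slice
#'
#' Applies the forward preprocessing (body crop, HU window, rescale),
#' predicts every axial slice independently with the trained model, stacks
#' the slice predictions, back-projects them into the original volume
#' geometry, and cleans the result (largest 6-connected component per lung
#' label; components below a small fraction of the total foreground are
#' dropped). Inference is deterministic for a fixed checkpoint.
#'
#' @param model a trained `seg_model`.
#' @param volume a [ct_volume()].
#' @param target_size slice size fed to the network; defaults to the size
#'   the model was trained at (or 256 x 256).
#' @param batch_slices how many slices to push through the network at once.
#' @param cleanup apply connected-component cleanup (default `TRUE`).
#' @param relabel enforce the left/right convention with
#'   [relabel_left_right()] after cleanup (default `TRUE`).
#' @param remove_dense also apply [remove_dense_areas()] (default `FALSE`;
#'   the primary masks deliberately include dense pathology).
#' @param min_component_frac components smaller than this fraction of the
#'   foreground are removed during cleanup.
#' @return A [lung_mask()] with the geometry of `volume`.
#' @export
segment_volume <- function(model, volume, target_size = NULL,
                           batch_slices = 16L, cleanup = TRUE, relabel = TRUE,
                           remove_dense = FALSE, min_component_frac = 0.005) {
  assert_that(inherits(model, "seg_model"), "model must be a seg_model")
  target_size <- target_size %||% model$input_size %||% c(256L, 256L)
  pp <- preprocess_volume(volume, target_size = target_size)
  nz <- dim(pp$images)[3]
  pred <- array(0L, c(target_size[1], target_size[2], nz))
  for (start in seq(1L, nz, by = batch_slices)) {
    zz <- start:min(start + batch_slices - 1L, nz)
    pred[, , zz] <- .net_predict(model$handle, pp$images[, , zz, drop = FALSE])
  }
  mask <- backproject_mask(pred, pp$transform, volume)
  if (cleanup) mask <- cleanup_mask(mask, min_component_frac)
  if (relabel) mask <- relabel_left_right(mask, volume)
  if (remove_dense) mask <- remove_dense_areas(mask, volume)
  mask
}

# keep the largest 6-connected component per lung label and drop any
# component smaller than min_frac of the total foreground
cleanup_mask <- function(mask, min_frac = 0.005) {
  lab <- mask$labels
  total_fg <- sum(lab > 0L)
  if (total_fg == 0L) return(mask)
  out <- array(0L, dim(lab))
  for (lv in c(1L, 2L)) {
    m <- lab == lv
    if (!any(m)) next
    comp <- label_components(m)
    sizes <- tabulate(comp[comp > 0L])
    keep <- which(sizes == max(sizes))[1]
    big_enough <- which(sizes >= min_frac * total_fg)
    keep <- union(keep, big_enough)
    out[array(comp %in% keep, dim(lab)) ] <- lv
  }
  lung_mask(out, mask$spacing, mask$origin, mask$id)
}

#' Remove dense areas from a lung mask
#'
#' Deletes mask voxels whose HU lies strictly inside (-50, 70) — the
#' density band of effusion and other fluid/soft-tissue-like material —
#' then repairs each lung label with a binary opening (ball radius 1) and
#' retains only its largest connected component. The repair can only delete
#' voxels: the output is always a subset of the input mask. Intended as an
#' optional post-processing step for comparability with ground truths that
#' exclude dense pathology; the primary masks keep it.
#'
#' @param mask a [lung_mask()].
#' @param volume the companion [ct_volume()] (same geometry).
#' @param hu_window open HU interval to remove (default `c(-50, 70)`,
#'   strict inequalities).
#' @return The filtered [lung_mask()].
#' @export
remove_dense_areas <- function(mask, volume, hu_window = c(-50, 70)) {
  check_same_geometry(mask, volume, "mask and volume")
  dense <- volume$voxels > hu_window[1] & volume$voxels < hu_window[2]
  out <- array(0L, dim(mask$labels))
  for (lv in c(1L, 2L)) {
    m <- mask$labels == lv & !dense
    if (!any(m)) next
    m <- binary_opening(m, 1) & m # opening is anti-extensive; keep subset explicit
    if (!any(m)) next
    m <- largest_component(m)
    out[m] <- lv
  }
  lung_mask(out, mask$spacing, mask$origin, mask$id)
}

#' Enforce the left/right labelling convention
#'
#' Label 1 is the right lung (lower x index under the LPS convention),
#' label 2 the left. Each foreground component receives one consistent
#' label from the side of the sagittal midline its centroid falls on (of
#' the body bounding box when a companion volume is given, else of the
#' mask bounding box); this both repairs mixed labels within a component
#' and recovers the convention when a model emits a degenerate labelling
#' (e.g. one class for both lungs). If the lungs form one fused component
#' spanning the midline it is split at the midline, conserving voxel
#' count. Only the largest component per side is kept; an empty mask
#' passes through unchanged.
#'
#' @param mask a [lung_mask()] or a binary mask in one.
#' @param volume optional companion [ct_volume()] used to locate the body
#'   midline.
#' @return A [lung_mask()] with consistent left/right labels.
#' @export
relabel_left_right <- function(mask, volume = NULL) {
  lab <- mask$labels
  if (!any(lab > 0L)) return(mask)
  if (!is.null(volume)) {
    body <- volume$voxels > -500
    xr <- range(which(apply(body, 3, any)))
  } else {
    xr <- range(which(apply(lab > 0L, 3, any)))
  }
  mid <- mean(xr)
  comp <- label_components(lab > 0L)
  ncomp <- max(comp)
  out <- array(0L, dim(lab))
  xcoord <- slice.index(lab, 3)
  if (ncomp == 1L) {
    xs <- which(apply(lab > 0L, 3, any))
    if (min(xs) < mid && max(xs) > mid) {
      # fused lungs: split at the sagittal midline, conserving voxel count
      out[lab > 0L & xcoord <= mid] <- 1L
      out[lab > 0L & xcoord > mid] <- 2L
      return(lung_mask(out, mask$spacing, mask$origin, mask$id))
    }
  }
  info <- lapply(seq_len(ncomp), function(k) {
    sel <- comp == k
    xcent <- mean(xcoord[sel])
    list(k = k, side = if (xcent <= mid) 1L else 2L, size = sum(sel))
  })
  for (side in c(1L, 2L)) {
    cand <- Filter(function(i) i$side == side, info)
    if (length(cand) == 0) next
    biggest <- cand[[which.max(vapply(cand, `[[`, 0, "size"))]]
    out[comp == biggest$k] <- side
  }
  lung_mask(out, mask$spacing, mask$origin, mask$id)
}
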