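#' Crop a CT volume to the body region
#'
#' Thresholds the volume at `body_threshold` HU, applies binary closing with
#' a voxel ball, keeps the largest 6-connected component (which drops the
#' patient table and other disconnected bright structures), and crops to its
#' tight 3-D bounding box plus a margin. One bounding box is used for the
#' whole volume so that slice geometry stays consistent within a scan.
#'
#' @param volume a [ct_volume()].
#' @param body_threshold HU threshold separating body from air (default
#'   -500).
#' @param closing_radius radius (voxels) of the ball used for binary
#'   closing.
#' @param margin margin (voxels) added around the bounding box, clipped to
#'   the volume bounds.
#' @return A list with `volume` (the cropped [ct_volume()]) and `transform`
#'   (a `crop_transform` that [backproject_mask()] can invert).
#' @export
crop_to_body <- function(volume, body_threshold = -500, closing_radius = 2,
                         margin = 2) {
  assert_that(inherits(volume, "ct_volume"), "volume must be a ct_volume")
  body <- volume$voxels > body_threshold
  if (!any(body)) abort("no body found: no voxel above the body threshold")
  body <- binary_closing(body, closing_radius)
  body <- largest_component(body)
  idx <- which(body, arr.ind = TRUE)
  d <- dim(volume$voxels)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, d)
  sub <- volume$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  tf <- structure(
    list(lo = as.integer(lo), hi = as.integer(hi), orig_shape = d,
         spacing = volume$spacing, target_size = c(256L, 256L)),
    class = "crop_transform"
  )
  list(volume = ct_volume(sub, volume$spacing, volume$origin, volume$id),
       transform = tf)
}

#' @export
print.crop_transform <- function(x, ...) {
  cat(sprintf("<crop_transform> bbox z[%d,%d] y[%d,%d] x[%d,%d] of %dx%dx%d\n",
              x$lo[1], x$hi[1], x$lo[2], x$hi[2], x$lo[3], x$hi[3],
              x$orig_shape[1], x$orig_shape[2], x$orig_shape[3]))
  invisible(x)
}

#' Window and normalise a slice of HU values
#'
#' Clips to the intensity window \[-1024, 600\] HU and maps it linearly onto
#' \[0, 1\]: `-1024 -> 0`, `600 -> 1`.
#'
#' @param slice_hu numeric matrix (or array) of HU values.
#' @param window length-2 HU window.
#' @return The normalised values, same shape, in \[0, 1\].
#' @export
normalize_slice <- function(slice_hu, window = c(-1024, 600)) {
  assert_that(all(is.finite(slice_hu)), "HU values must be finite")
  v <- pmin(pmax(slice_hu, window[1]), window[2])
  (v - window[1]) / (window[2] - window[1])
}

#' Resize a 2-D slice
#'
#' Bilinear interpolation for intensity images, nearest-neighbour for label
#' slices (so no new labels can be invented). The slice is stretched
#' anisotropically to exactly `target_size`; no aspect-ratio padding.
#'
#' @param image numeric matrix.
#' @param target_size integer length-2 `(rows, cols)`, default
#'   `c(256, 256)`.
#' @param labels if `TRUE`, use nearest-neighbour interpolation.
#' @return The resized matrix.
#' @export
resize_slice <- function(image, target_size = c(256L, 256L), labels = FALSE) {
  assert_that(is.matrix(image) && all(dim(image) > 0), "image must be a non-empty matrix")
  assert_that(all(target_size >= 1), "target_size must be positive")
  .cpp_resize2d(image, as.integer(target_size[1]), as.integer(target_size[2]), labels)
}

#' Preprocess a volume into a stack of network-ready slices
#'
#' Applies the full forward chain: body crop, HU windowing to \[0, 1\], and
#' per-slice rescale to `target_size`.
#'
#' @param volume a [ct_volume()].
#' @param target_size slice size `(rows, cols)` fed to the network.
#' @param window HU window for [normalize_slice()].
#' @param ... passed to [crop_to_body()].
#' @return A list with `images` (array `target_size[1] x target_size[2] x
#'   n_slices`) and `transform` (the `crop_transform`, with `target_size`
#'   recorded).
#' @export
preprocess_volume <- function(volume, target_size = c(256L, 256L),
                              window = c(-1024, 600), ...) {
  cr <- crop_to_body(volume, ...)
  cr$transform$target_size <- as.integer(target_size)
  vox <- cr$volume$voxels
  nz <- dim(vox)[1]
  images <- array(0, c(target_size[1], target_size[2], nz))
  for (z in seq_len(nz)) {
    images[, , z] <- resize_slice(normalize_slice(vox[z, , ], window),
                                  target_size, labels = FALSE)
  }
  list(images = images, transform = cr$transform)
}

# forward-transform a label volume the same way as the images (nearest)
forward_mask_slices <- function(mask, transform) {
  lab <- mask$labels[transform$lo[1]:transform$hi[1],
                     transform$lo[2]:transform$hi[2],
                     transform$lo[3]:transform$hi[3], drop = FALSE]
  nz <- dim(lab)[1]
  out <- array(0L, c(transform$target_size, nz))
  for (z in seq_len(nz)) {
    out[, , z] <- resize_slice(lab[z, , ], transform$target_size, labels = TRUE)
  }
  out
}

#' Back-project slice predictions into the original volume geometry
#'
#' Inverts the crop + rescale mapping: each predicted slice is resized
#' (nearest-neighbour) back to the bounding-box in-plane size and placed at
#' its position in the original grid; everything outside the body crop is
#' background. Needed because evaluation runs on the 3-D volumes while
#' prediction runs per slice.
#'
#' @param mask_stack integer array `(H, W, n_slices)` of predicted labels.
#' @param transform the `crop_transform` produced when preprocessing the
#'   reference volume.
#' @param reference the original [ct_volume()].
#' @return A [lung_mask()] aligned with `reference`.
#' @export
backproject_mask <- function(mask_stack, transform, reference) {
  assert_that(inherits(transform, "crop_transform"), "transform must be a crop_transform")
  assert_that(inherits(reference, "ct_volume"), "reference must be a ct_volume")
  d <- dim(reference$voxels)
  assert_that(identical(transform$orig_shape, d),
              "transform does not match the reference volume")
  nz <- transform$hi[1] - transform$lo[1] + 1L
  assert_that(dim(mask_stack)[3] == nz,
              "prediction stack depth does not match the cropped volume")
  ny <- transform$hi[2] - transform$lo[2] + 1L
  nx <- transform$hi[3] - transform$lo[3] + 1L
  out <- array(0L, d)
  for (z in seq_len(nz)) {
    sl <- resize_slice(mask_stack[, , z], c(ny, nx), labels = TRUE)
    out[transform$lo[1] + z - 1L,
        transform$lo[2]:transform$hi[2],
        transform$lo[3]:transform$hi[3]] <- as.integer(sl)
  }
  lung_mask(out, reference$spacing, reference$origin, reference$id)
}
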