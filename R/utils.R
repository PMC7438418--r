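# Internal helpers shared across modules. All volumetric arrays follow the
# package-wide (z, y, x) axis order under the LPS anatomical convention:
# x grows toward the patient's Left, y toward Posterior, z toward Superior.

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# offsets (rows dz, dy, dx) of a voxel ball of given radius, used as a
# structuring element for 3-D morphology
ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  keep <- g$dz^2 + g$dy^2 + g$dx^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

binary_dilate <- function(mask, radius = 1) {
  d <- dim(mask)
  .cpp_morph3d(as.logical(mask), d[1], d[2], d[3], ball_offsets(radius), TRUE)
}

binary_erode <- function(mask, radius = 1) {
  d <- dim(mask)
  .cpp_morph3d(as.logical(mask), d[1], d[2], d[3], ball_offsets(radius), FALSE)
}

binary_closing <- function(mask, radius = 1) {
  binary_erode(binary_dilate(mask, radius), radius)
}

binary_opening <- function(mask, radius = 1) {
  binary_dilate(binary_erode(mask, radius), radius)
}

label_components <- function(mask) {
  d <- dim(mask)
  .cpp_label3d(as.logical(mask), d[1], d[2], d[3])
}

# largest 6-connected component of a binary array (all FALSE -> all FALSE)
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(array(FALSE, dim(mask)))
  sizes <- tabulate(lab[lab > 0L])
  array(lab == which.max(sizes), dim(mask))
}

# border voxels: foreground with at least one 6-neighbour outside the
# foreground (array edges count as background)
surface_voxels <- function(mask) {
  d <- dim(mask)
  m <- array(as.logical(mask), d)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- function(dz, dy, dx) {
    pad[(2:(d[1] + 1)) + dz, (2:(d[2] + 1)) + dy, (2:(d[3] + 1)) + dx]
  }
  nb <- core(-1, 0, 0) & core(1, 0, 0) & core(0, -1, 0) &
    core(0, 1, 0) & core(0, 0, -1) & core(0, 0, 1)
  m & !nb
}

# voxel-centre coordinates (mm) of TRUE voxels, columns z, y, x
surface_coords_mm <- function(surface, spacing) {
  idx <- which(surface, arr.ind = TRUE)
  sweep(idx - 1, 2, spacing, `*`)
}

# derive a stream of 31-bit sub-seeds from one master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}
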