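#' CT volume container
#'
#' An in-memory 3-D CT scan in Hounsfield units (HU). Voxels are stored in
#' the package-wide `(z, y, x)` axis order under the LPS anatomical
#' convention (x toward patient Left, y toward Posterior, z toward
#' Superior), so the right lung sits at lower x indices.
#'
#' @param voxels 3-D numeric array `(z, y, x)` of HU values.
#' @param spacing numeric length-3, voxel size in mm per axis `(z, y, x)`;
#'   all strictly positive.
#' @param origin numeric length-3, LPS position (mm) of the first voxel
#'   centre.
#' @param id case identifier string.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0), id = "case") {
  assert_that(is.array(voxels) && length(dim(voxels)) == 3,
              "voxels must be a 3-D array (z, y, x)")
  assert_that(is.numeric(spacing) && length(spacing) == 3 && all(spacing > 0),
              "spacing must be three strictly positive numbers (z, y, x)")
  assert_that(all(is.finite(voxels)), "voxel values must be finite")
  rng <- range(voxels)
  if (rng[1] < -1100 || rng[2] > 3100) {
    warn(sprintf("HU values outside the expected [-1100, 3100] range: [%g, %g]",
                 rng[1], rng[2]))
  }
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         origin = as.numeric(origin), id = as.character(id)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume '%s'> %d x %d x %d voxels (z,y,x), spacing %.3g/%.3g/%.3g mm, HU [%d, %d]\n",
              x$id, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              round(min(x$voxels)), round(max(x$voxels))))
  invisible(x)
}

#' Lung label mask container
#'
#' Integer label volume geometrically aligned with a [ct_volume()]:
#' 0 = background, 1 = right lung, 2 = left lung.
#'
#' @param labels 3-D integer array `(z, y, x)` with values in \{0, 1, 2\}.
#' @param spacing,origin geometry, as for [ct_volume()]; usually copied from
#'   the companion volume.
#' @param id case identifier string.
#' @return An object of class `lung_mask`.
#' @export
lung_mask <- function(labels, spacing, origin = c(0, 0, 0), id = "case") {
  assert_that(is.array(labels) && length(dim(labels)) == 3,
              "labels must be a 3-D array (z, y, x)")
  assert_that(all(labels %in% 0:2), "mask labels must be within {0, 1, 2}")
  assert_that(is.numeric(spacing) && length(spacing) == 3 && all(spacing > 0),
              "spacing must be three strictly positive numbers (z, y, x)")
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, spacing = as.numeric(spacing),
         origin = as.numeric(origin), id = as.character(id)),
    class = "lung_mask"
  )
}

#' @export
print.lung_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<lung_mask '%s'> %d x %d x %d voxels, right %d / left %d foreground voxels\n",
              x$id, d[1], d[2], d[3], sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

check_same_geometry <- function(a, b, what = "objects") {
  arr_a <- if (inherits(a, "ct_volume")) a$voxels else a$labels
  arr_b <- if (inherits(b, "ct_volume")) b$voxels else b$labels
  assert_that(identical(dim(arr_a), dim(arr_b)),
              sprintf("%s must share the same voxel grid shape", what))
  assert_that(max(abs(a$spacing - b$spacing)) < 1e-6,
              sprintf("%s must share the same voxel spacing", what))
  invisible(TRUE)
}

# LPS affine for our canonical (z,y,x) layout; NIfTI world space is RAS
lps_affine <- function(spacing, origin) {
  # NIfTI array axes (i,j,k) = our (x,y,z); RAS = (-L, -P, S)
  rbind(c(-spacing[3], 0, 0, -origin[3]),
        c(0, -spacing[2], 0, -origin[2]),
        c(0, 0, spacing[1], origin[1]),
        c(0, 0, 0, 1))
}

nifti_from_canonical <- function(arr_zyx, spacing, origin) {
  img <- RNifti::asNifti(aperm(arr_zyx, c(3, 2, 1)))
  RNifti::qform(img) <- structure(lps_affine(spacing, origin), code = 2L)
  RNifti::pixdim(img) <- spacing[c(3, 2, 1)]
  img
}

#' Write a CT volume as NIfTI
#'
#' Voxels are stored as `int16` clipped to \[-1024, 3071\] HU with LPS
#' geometry encoded in the qform.
#'
#' @param volume a [ct_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  assert_that(inherits(volume, "ct_volume"), "volume must be a ct_volume")
  vox <- round(pmin(pmax(volume$voxels, -1024), 3071))
  img <- nifti_from_canonical(vox, volume$spacing, volume$origin)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Write a lung mask as NIfTI
#'
#' Stored as `uint8` with geometry headers taken from the mask (which must
#' match its companion volume when one is supplied).
#'
#' @param mask a [lung_mask()].
#' @param path output `.nii` or `.nii.gz` path.
#' @param reference optional companion [ct_volume()]; a geometry mismatch is
#'   an error.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, reference = NULL) {
  assert_that(inherits(mask, "lung_mask"), "mask must be a lung_mask")
  if (!is.null(reference)) check_same_geometry(mask, reference, "mask and reference volume")
  img <- nifti_from_canonical(mask$labels, mask$spacing, mask$origin)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

read_nifti_canonical <- function(path) {
  img <- RNifti::readNifti(path)
  RNifti::orientation(img) <- "LPS"
  arr <- aperm(as.array(img), c(3, 2, 1))
  spc <- RNifti::pixdim(img)[c(3, 2, 1)]
  assert_that(all(spc > 0), sprintf("missing or invalid voxel spacing in %s", path))
  xf <- RNifti::xform(img)
  origin <- c(xf[3, 4], -xf[2, 4], -xf[1, 4]) # RAS translation back to LPS (z,y,x)
  list(arr = arr, spacing = spc, origin = origin)
}

#' Read a CT volume
#'
#' Reads a NIfTI file or a directory containing a single DICOM CT series.
#' Voxels are returned in true HU (the DICOM rescale slope/intercept is
#' applied) and the volume is reoriented to the canonical LPS `(z, y, x)`
#' layout.
#'
#' @param path a `.nii`/`.nii.gz` file or a directory of DICOM slices.
#' @param id optional case id; defaults to the file name or the DICOM
#'   SeriesInstanceUID.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, id = NULL) {
  if (dir.exists(path)) return(read_dicom_series(path, id = id))
  assert_that(file.exists(path), sprintf("no such file: %s", path))
  x <- read_nifti_canonical(path)
  ct_volume(x$arr, x$spacing, x$origin,
            id = id %||% sub("\\.nii(\\.gz)?$", "", basename(path)))
}

#' Read a lung mask from NIfTI
#'
#' @param path NIfTI path.
#' @param reference optional [ct_volume()] whose geometry the mask must match.
#' @param id optional case id.
#' @return A [lung_mask()].
#' @export
read_mask <- function(path, reference = NULL, id = NULL) {
  x <- read_nifti_canonical(path)
  m <- lung_mask(x$arr, x$spacing, x$origin,
                 id = id %||% sub("\\.nii(\\.gz)?$", "", basename(path)))
  if (!is.null(reference)) check_same_geometry(m, reference, "mask and reference volume")
  m
}

# ---------------------------------------------------------------------------
# Minimal DICOM series reader (CT Image Storage, little-endian transfer
# syntaxes, uncompressed pixel data). Only the handful of tags the pipeline
# needs are decoded.
# ---------------------------------------------------------------------------

dcm_u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
dcm_u32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  assert_that(length(raw) > 132 && rawToChar(raw[129:132]) == "DICM",
              sprintf("%s is not a DICOM part-10 file", path))
  pos <- 133L
  tags <- list()
  explicit <- TRUE
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8 <= length(raw)) {
    group <- dcm_u16(raw[pos:(pos + 1)]); elem <- dcm_u16(raw[(pos + 2):(pos + 3)])
    key <- sprintf("%04x,%04x", group, elem)
    if (explicit || group == 2L) {
      vr <- rawToChar(raw[(pos + 4):(pos + 5)])
      if (vr %in% long_vrs) {
        len <- dcm_u32(raw[(pos + 8):(pos + 11)]); hdr <- 12L
      } else {
        len <- dcm_u16(raw[(pos + 6):(pos + 7)]); hdr <- 8L
      }
    } else {
      vr <- ""; len <- dcm_u32(raw[(pos + 4):(pos + 7)]); hdr <- 8L
    }
    if (len == 4294967295) abort("undefined-length DICOM elements are not supported")
    val_start <- pos + hdr
    if (val_start + len - 1 > length(raw)) abort(sprintf("truncated DICOM element %s", key))
    tags[[key]] <- list(vr = vr, raw = raw[seq_len(len) + val_start - 1L])
    if (key == "0002,0010") {
      ts <- sub("\\s+$", "", rawToChar(tags[[key]]$raw))
      ts <- gsub("\\x00", "", ts, useBytes = TRUE)
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (ts != "1.2.840.10008.1.2.1")
        abort(sprintf("unsupported DICOM transfer syntax: %s", ts))
    }
    pos <- val_start + len
  }
  tags
}

dcm_string <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) return(NULL)
  s <- rawToChar(v$raw[v$raw != as.raw(0)])
  sub("^\\s+|\\s+$", "", s)
}

dcm_numbers <- function(tags, key) {
  s <- dcm_string(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_uint16_value <- function(tags, key) {
  v <- tags[[key]]
  if (is.null(v)) return(NULL)
  dcm_u16(v$raw[1:2])
}

read_dicom_series <- function(dir, id = NULL) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  assert_that(length(files) > 0, sprintf("no files in DICOM directory %s", dir))
  slices <- lapply(files, function(f) {
    tags <- parse_dicom_file(f)
    uid <- dcm_string(tags, "0020,000e")
    ipp <- dcm_numbers(tags, "0020,0032")
    iop <- dcm_numbers(tags, "0020,0037") %||% c(1, 0, 0, 0, 1, 0)
    ps <- dcm_numbers(tags, "0028,0030")
    rows <- dcm_uint16_value(tags, "0028,0010")
    cols <- dcm_uint16_value(tags, "0028,0011")
    slope <- (dcm_numbers(tags, "0028,1053") %||% 1)[1]
    intercept <- (dcm_numbers(tags, "0028,1052") %||% 0)[1]
    pixrep <- dcm_uint16_value(tags, "0028,0103") %||% 1L
    pd <- tags[["7fe0,0010"]]
    assert_that(!is.null(uid), sprintf("%s: missing SeriesInstanceUID", f))
    assert_that(!is.null(ipp), sprintf("%s: missing ImagePositionPatient", f))
    assert_that(!is.null(ps), sprintf("%s: missing PixelSpacing", f))
    assert_that(!is.null(pd), sprintf("%s: missing PixelData", f))
    stored <- readBin(pd$raw, "integer", n = rows * cols, size = 2,
                      signed = (pixrep == 1L), endian = "little")
    # DICOM pixel matrix is row-major: fastest index runs along a row
    # (increasing column); build the (rows, cols) matrix accordingly
    m <- matrix(stored, nrow = cols, ncol = rows)
    hu <- slope * t(m) + intercept
    normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
                iop[3] * iop[4] - iop[1] * iop[6],
                iop[1] * iop[5] - iop[2] * iop[4])
    list(uid = uid, zpos = sum(ipp * normal), ipp = ipp, ps = ps, hu = hu)
  })
  uids <- vapply(slices, `[[`, "", "uid")
  assert_that(length(unique(uids)) == 1,
              sprintf("directory %s mixes %d DICOM series", dir, length(unique(uids))))
  ord <- order(vapply(slices, `[[`, 0, "zpos"))
  z <- vapply(slices, `[[`, 0, "zpos")[ord]
  if (length(z) > 1) {
    dz <- diff(z)
    assert_that(all(dz > 0), "non-monotone DICOM slice positions")
    spacing_z <- stats::median(dz)
  } else {
    abort("a DICOM series needs at least two slices to determine spacing")
  }
  ps <- slices[[1]]$ps
  d2 <- dim(slices[[1]]$hu)
  vox <- array(0, c(length(ord), d2[1], d2[2]))
  for (i in seq_along(ord)) vox[i, , ] <- slices[[ord[i]]]$hu
  # patient coordinates are already LPS; identity axial orientation assumed
  # (rows along y, columns along x); z index ascends toward Superior
  origin <- c(z[1], slices[[ord[1]]]$ipp[2], slices[[ord[1]]]$ipp[1])
  ct_volume(vox, c(spacing_z, ps[1], ps[2]), origin, id = id %||% uids[1])
}
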