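# Shared fixtures, built in code at test time.

# smallest legal phantom; cheap enough for per-test generation
tiny_spec <- function(...) {
  phantom_spec(shape = c(16L, 48L, 48L), spacing = c(5, 2, 2), ...)
}

tiny_case <- function(seed = 1L, pathology = "none", ...) {
  mix <- setNames(1, pathology)
  generate_phantom(tiny_spec(pathology_mix = mix, ...), seed)
}

# brute-force all-pairs surface-distance oracle, independent of the
# EDT-based implementation: plain R, explicit pairwise distances
oracle_surface_distances <- function(x, y, spacing) {
  sx <- thoraxseg:::surface_voxels(x)
  sy <- thoraxseg:::surface_voxels(y)
  cx <- thoraxseg:::surface_coords_mm(sx, spacing)
  cy <- thoraxseg:::surface_coords_mm(sy, spacing)
  nearest <- function(a, b) {
    apply(a, 1, function(p) sqrt(min(colSums((t(b) - p)^2))))
  }
  list(dxy = nearest(cx, cy), dyx = nearest(cy, cx))
}

oracle_hd95 <- function(x, y, spacing) {
  d <- oracle_surface_distances(x, y, spacing)
  max(quantile(d$dxy, 0.95, names = FALSE), quantile(d$dyx, 0.95, names = FALSE))
}

oracle_msd <- function(x, y, spacing) {
  d <- oracle_surface_distances(x, y, spacing)
  max(mean(d$dxy), mean(d$dyx))
}

# random blob-ish binary mask: union of a few random boxes, guaranteed
# non-empty
random_mask <- function(dims = c(20L, 20L, 20L), n_boxes = 3L) {
  m <- array(FALSE, dims)
  for (i in seq_len(n_boxes)) {
    lo <- pmax(1L, as.integer(runif(3, 1, dims - 3)))
    hi <- pmin(dims, lo + as.integer(runif(3, 1, 6)))
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  m
}

# ---------------------------------------------------------------------------
# minimal DICOM writer (explicit VR little endian) used to exercise the
# package's reader; intentionally separate from the reader's code paths
# ---------------------------------------------------------------------------

dcm_raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0))
  hdr <- c(dcm_raw_u16(group), dcm_raw_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0, 0)), dcm_raw_u32(length(value_raw)), value_raw)
  } else {
    c(hdr, dcm_raw_u16(length(value_raw)), value_raw)
  }
}

dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, charToRaw(s))

# write one axial CT slice; `stored` is the raw pixel matrix (y, x) BEFORE
# rescale; HU = slope * stored + intercept
write_test_dicom <- function(path, stored, ipp = c(0, 0, 0), series_uid = "1.2.3.4",
                             slope = 1, intercept = -1024,
                             pixel_spacing = c(1, 1)) {
  rows <- nrow(stored); cols <- ncol(stored)
  # pixel data in row-major order (row by row)
  pix <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
  meta <- c(
    dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  body <- c(
    dcm_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_str(0x0020, 0x000e, "UI", series_uid),
    dcm_str(0x0020, 0x0032, "DS", paste(ipp[c(3, 2, 1)], collapse = "\\")),
    dcm_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
    dcm_element(0x0028, 0x0010, "US", dcm_raw_u16(rows)),
    dcm_element(0x0028, 0x0011, "US", dcm_raw_u16(cols)),
    dcm_str(0x0028, 0x0030, "DS", paste(pixel_spacing, collapse = "\\")),
    dcm_element(0x0028, 0x0100, "US", dcm_raw_u16(16)),
    dcm_element(0x0028, 0x0103, "US", dcm_raw_u16(1)),
    dcm_str(0x0028, 0x1052, "DS", as.character(intercept)),
    dcm_str(0x0028, 0x1053, "DS", as.character(slope)),
    dcm_element(0x7fe0, 0x0010, "OW", pix)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# a trained tiny model is expensive; build once per test run and reuse
trained_tiny_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- phantom_spec(shape = c(16L, 48L, 48L), spacing = c(5, 2, 2),
                         pathology_mix = c(none = 1))
    cases <- generate_cohort(spec, 8, seed = 70)
    rec <- slice_records(cases, target_size = c(48L, 48L))
    model <- withr::with_seed(7, build_model(net_config("unet", base_width = 8, depth = 4)))
    model <- train_model(model, rec,
                         train_config(epochs = 16, seed = 7, lr = 0.1,
                                      val_fraction = 0))
    cache <<- model
    model
  }
})
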